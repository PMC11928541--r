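#' Aggregation methods
#'
#' The seven rules collapsing a TLS's tile predictions into one
#' structure-level maturation class, on the ordinal encoding 0 = Aggregate,
#' 1 = Non-GC, 2 = GC:
#'
#' * `majority` -- the most frequent tile label;
#' * `average` -- the mean tile label rounded to the nearest class;
#' * `median` -- the median tile label rounded to the nearest class (the
#'   median of an even count may be half-integer);
#' * `mode` -- the most frequent tile label (equivalent to `majority`; both
#'   are defined identically and share one code path);
#' * `soft_voting` -- argmax of the element-wise mean probability vector;
#' * `custom` -- maturity priority: GC if any tile is GC, else Non-GC if any
#'   tile is Non-GC, else Aggregate;
#' * `max_confidence` -- the label of the single most confident tile
#'   (confidence = the tile's maximum class probability).
#'
#' All ties (tied counts, tied mean probabilities, `.5` roundings, tied
#' confidences with differing labels) resolve toward the more mature class
#' and are flagged via `tie_broken`.
#'
#' @format character vector of the seven method names.
#' @export
AGGREGATION_METHODS <- c("majority", "average", "median", "mode",
                         "soft_voting", "custom", "max_confidence")

prob_cols <- c("p_aggregate", "p_nongc", "p_gc")

check_simplex <- function(P) {
  if (any(P < -1e-9) || any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("tile probability vectors must be non-negative and sum to 1",
         call. = FALSE)
  }
}

# argmax resolving ties toward the higher (more mature) class
argmax_mature <- function(x) {
  m <- max(x)
  top <- which(x >= m - 1e-12)
  list(idx = top[length(top)], tie = length(top) > 1L)
}

# half-up rounding (toward maturity on the ordinal scale)
round_mature <- function(x) {
  list(value = floor(x + 0.5), tie = abs(x - floor(x) - 0.5) < 1e-12)
}

tile_labels <- function(pred) {
  if (!is.null(pred$pred_class)) return(class_code(pred$pred_class))
  P <- as.matrix(pred[, prob_cols])
  apply(P, 1L, function(p) argmax_mature(p)$idx - 1L)
}

#' Aggregate one TLS's tile predictions into a structure-level class
#'
#' @param predictions data.frame of tile predictions for a single TLS with
#'   probability columns `p_aggregate`, `p_nongc`, `p_gc` (and optionally
#'   `pred_class`, `confidence`, `tls_id`).
#' @param method one of [AGGREGATION_METHODS].
#' @return one-row data.frame: `tls_id`, `method`, `pred_class`, `support`
#'   (number of tiles), `tie_broken`.
#' @examples
#' p <- data.frame(p_aggregate = c(0.6, 0.1), p_nongc = c(0.3, 0.1),
#'                 p_gc = c(0.1, 0.8))
#' aggregate_tls(p, "max_confidence")
#' @export
aggregate_tls <- function(predictions, method) {
  if (!is.character(method) || length(method) != 1L ||
      !(method %in% AGGREGATION_METHODS)) {
    stopf("unknown aggregation method '%s'; available: %s",
          paste(method, collapse = ","),
          paste(AGGREGATION_METHODS, collapse = ", "))
  }
  n <- nrow(predictions)
  if (is.null(n) || n == 0L) {
    stop("cannot aggregate an empty prediction list (a TLS without tiles is excluded upstream)",
         call. = FALSE)
  }
  P <- as.matrix(predictions[, prob_cols])
  check_simplex(P)
  labels <- tile_labels(predictions)
  tie <- FALSE

  cls <- switch(method,
    majority = ,
    mode = {
      counts <- tabulate(labels + 1L, 3L)
      r <- argmax_mature(counts)
      tie <- r$tie
      r$idx - 1L
    },
    average = {
      r <- round_mature(mean(labels))
      tie <- r$tie
      r$value
    },
    median = {
      r <- round_mature(stats::median(labels))
      tie <- r$tie
      r$value
    },
    soft_voting = {
      r <- argmax_mature(colMeans(P))
      tie <- r$tie
      r$idx - 1L
    },
    custom = {
      if (any(labels == 2L)) 2L else if (any(labels == 1L)) 1L else 0L
    },
    max_confidence = {
      conf <- if (!is.null(predictions$confidence)) predictions$confidence
              else apply(P, 1L, max)
      top <- which(conf >= max(conf) - 1e-12)
      top_labels <- unique(labels[top])
      tie <- length(top_labels) > 1L
      max(top_labels)
    })

  data.frame(
    tls_id = if (!is.null(predictions$tls_id)) predictions$tls_id[1L] else NA_character_,
    method = method, pred_class = as.integer(cls), support = n,
    tie_broken = tie, stringsAsFactors = FALSE)
}

#' Aggregate tile predictions for many TLS under several methods
#'
#' @param predictions tile-prediction data.frame with a `tls_id` grouping
#'   column; duplicate `tile_id`s within a TLS are an integrity error.
#' @param methods subset of [AGGREGATION_METHODS] (default: all seven).
#' @return data.frame with `|TLS| x |methods|` rows, ordered by `tls_id`
#'   then method.
#' @export
aggregate_all <- function(predictions, methods = AGGREGATION_METHODS) {
  if (is.null(predictions$tls_id)) {
    stop("predictions must carry a tls_id grouping column", call. = FALSE)
  }
  bad <- setdiff(methods, AGGREGATION_METHODS)
  if (length(bad)) {
    stopf("unknown aggregation method '%s'; available: %s",
          paste(bad, collapse = ", "),
          paste(AGGREGATION_METHODS, collapse = ", "))
  }
  if (!is.null(predictions$tile_id)) {
    key <- paste(predictions$tls_id, predictions$tile_id, sep = "\r")
    if (anyDuplicated(key)) {
      stopf("duplicate tile_id within TLS: %s",
            paste(unique(predictions$tls_id[duplicated(key)]), collapse = ", "))
    }
  }
  groups <- split(seq_len(nrow(predictions)),
                  factor(predictions$tls_id, levels = sort(unique(predictions$tls_id))))
  rows <- vector("list", length(groups) * length(methods))
  j <- 0L
  for (g in groups) {
    sub <- predictions[g, , drop = FALSE]
    for (m in methods) {
      j <- j + 1L
      rows[[j]] <- aggregate_tls(sub, m)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Error amplification of the maturity-priority (custom) rule
#'
#' Probability that the custom aggregation mislabels a true-Aggregate TLS
#' when each of its `n_tiles` tiles is independently misread as a more
#' mature class with probability `epsilon`: any single false-positive tile
#' flips the whole structure, so the closed form is
#' `1 - (1 - epsilon)^n_tiles`.  Strictly increasing in `n_tiles` for
#' `epsilon` in (0,1) -- the mechanism behind the custom rule's sensitivity
#' to tile-prediction errors.
#'
#' @param epsilon per-tile false-positive rate in `[0, 1]`.
#' @param n_tiles number of tiles (>= 1); vectorized.
#' @return numeric vector of mislabeling probabilities.
#' @examples
#' custom_error_curve(0.05, c(5, 15, 30))
#' @export
custom_error_curve <- function(epsilon, n_tiles) {
  if (any(epsilon < 0) || any(epsilon > 1)) {
    stop("epsilon must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_tiles < 1)) stop("n_tiles must be >= 1", call. = FALSE)
  1 - (1 - epsilon)^n_tiles
}

#' Monte-Carlo estimate of the custom rule's mislabeling probability
#'
#' Simulates `reps` true-Aggregate TLS of `n_tiles` tiles through
#' [corrupt_predictions()] with all tile errors sent to GC, aggregates each
#' with the custom rule, and returns the fraction mislabeled.  Agrees with
#' [custom_error_curve()] within binomial sampling error.
#'
#' @inheritParams custom_error_curve
#' @param reps number of simulated TLS.
#' @param seed integer seed.
#' @return list with `estimate`, `se` (binomial standard error), `reps`.
#' @export
custom_error_mc <- function(epsilon, n_tiles, reps = 10000, seed = 1) {
  kernel <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, byrow = TRUE)
  preds <- corrupt_predictions(rep(0L, n_tiles * reps), epsilon,
                               confusion_kernel = kernel, seed = seed)
  preds$tls_id <- rep(sprintf("mc_%06d", seq_len(reps)), each = n_tiles)
  agg <- aggregate_all(preds, "custom")
  est <- mean(agg$pred_class != 0L)
  list(estimate = est, se = sqrt(est * (1 - est) / reps), reps = reps)
}
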