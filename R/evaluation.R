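#' Multiclass confusion matrix
#'
#' Rows index the true class, columns the predicted class, both ordered
#' (Aggregate, Non-GC, GC).
#'
#' @param true,pred equal-length vectors of maturation classes (labels or
#'   codes 0/1/2).
#' @return object of class `tls_confusion`: a 3x3 integer matrix with an
#'   `n` attribute.
#' @examples
#' confusion_matrix(c(0, 1, 2), c(0, 1, 2))
#' @export
confusion_matrix <- function(true, pred) {
  if (length(true) != length(pred)) {
    stopf("length mismatch: %d true vs %d predicted labels",
          length(true), length(pred))
  }
  if (!length(true)) stop("need at least one observation", call. = FALSE)
  t_ <- factor(class_code(true), levels = 0:2, labels = TLS_CLASS_LABELS)
  p_ <- factor(class_code(pred), levels = 0:2, labels = TLS_CLASS_LABELS)
  counts <- unclass(table(true = t_, predicted = p_))
  structure(counts, n = sum(counts), class = c("tls_confusion", "matrix"))
}

#' @export
print.tls_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted), n =",
      attr(x, "n"), "\n")
  print(unclass(x))
  cat(sprintf("accuracy %.4f; Cohen's kappa %.4f (%s)\n", accuracy(x),
              cohens_kappa(x)$kappa, cohens_kappa(x)$band))
  invisible(x)
}

#' @export
plot.tls_confusion <- function(x, ...) {
  m <- normalize_confusion(x)
  m[is.na(m)] <- 0
  graphics::image(1:3, 1:3, t(m[3:1, ]), axes = FALSE, xlab = "predicted",
                  ylab = "true", col = grDevices::hcl.colors(25, "Blues 3",
                                                             rev = TRUE), ...)
  graphics::axis(1, 1:3, TLS_CLASS_LABELS)
  graphics::axis(2, 3:1, TLS_CLASS_LABELS, las = 2)
  for (i in 1:3) for (j in 1:3) {
    graphics::text(j, 4 - i, sprintf("%.1f%%", m[i, j]))
  }
  invisible(m)
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm a [confusion_matrix()] (or plain 3x3 count matrix).
#' @return fraction of agreeing observations, `trace / n`.
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  sum(diag(cm)) / sum(cm)
}

#' Row-normalized (per-true-class) percentage matrix
#'
#' Each row is scaled to percentages of its true-class support, matching
#' per-class correct-prediction rates.  Rows with zero support are returned
#' as `NA` (undefined), not zero.  Column normalization (per predicted
#' class) is available via `by = "pred"`.
#'
#' @param cm a [confusion_matrix()].
#' @param by `"true"` (default) or `"pred"`.
#' @return 3x3 numeric matrix of percentages; defined rows sum to 100.
#' @export
normalize_confusion <- function(cm, by = c("true", "pred")) {
  by <- match.arg(by)
  m <- as.matrix(unclass(cm))
  if (by == "pred") m <- t(m)
  s <- rowSums(m)
  out <- 100 * m / ifelse(s > 0, s, NA_real_)
  if (by == "pred") out <- t(out)
  out
}

#' Cohen's kappa with agreement band
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o = trace / n` and `p_e = sum_i rowsum_i * colsum_i / n^2`.  The
#' agreement band follows the conventional cutpoints: minimal (<= 0.20),
#' fair (0.20, 0.40], moderate (0.40, 0.60], substantial (0.60, 0.80],
#' almost perfect (0.80, 1].  The degenerate case `p_e = 1` (all mass in a
#' single category for both raters) yields `kappa = NA` with band
#' `"undefined"` rather than NaN propagation.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `kappa`, `band`, `p_o`, `p_e`.
#' @examples
#' cm <- confusion_matrix(rep(0:2, c(5, 5, 5)),
#'                        c(0,0,0,0,1, 0,1,1,1,2, 1,2,2,2,2))
#' cohens_kappa(cm)
#' @export
cohens_kappa <- function(cm) {
  m <- as.matrix(unclass(cm))
  n <- sum(m)
  if (n <= 0) stop("confusion matrix is empty", call. = FALSE)
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    return(list(kappa = NA_real_, band = "undefined", p_o = p_o, p_e = p_e))
  }
  k <- (p_o - p_e) / (1 - p_e)
  list(kappa = k, band = kappa_band(k), p_o = p_o, p_e = p_e)
}

#' @rdname cohens_kappa
#' @param kappa numeric kappa value(s).
#' @export
kappa_band <- function(kappa) {
  vapply(kappa, function(k) {
    if (is.na(k)) "undefined"
    else if (k <= 0.20) "minimal"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial"
    else "almost_perfect"
  }, "")
}

#' Full metrics report for one truth/prediction pairing
#'
#' @param true,pred class vectors (see [confusion_matrix()]).
#' @return object of class `metrics_report`: list with `confusion`
#'   (`tls_confusion`), `normalized` (row-stochastic percentages),
#'   `accuracy`, `kappa`, `kappa_band`, `n`.
#' @export
metrics_report <- function(true, pred) {
  cm <- confusion_matrix(true, pred)
  kp <- cohens_kappa(cm)
  structure(list(confusion = cm, normalized = normalize_confusion(cm),
                 accuracy = accuracy(cm), kappa = kp$kappa,
                 kappa_band = kp$band, n = attr(cm, "n")),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics (n = %d): accuracy %.4f, kappa %.4f (%s)\n", x$n,
              x$accuracy, x$kappa, x$kappa_band))
  print(unclass(x$confusion))
  invisible(x)
}

#' Write / read a metrics report as JSON
#'
#' @param report a [metrics_report()].
#' @param path JSON path.
#' @return `write_metrics_json()`: `path` invisibly; `read_metrics_json()`:
#'   a `metrics_report`.
#' @export
write_metrics_json <- function(report, path) {
  obj <- list(accuracy = report$accuracy, kappa = report$kappa,
              kappa_band = report$kappa_band, n = report$n,
              confusion = unclass(report$confusion),
              normalized = report$normalized)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
read_metrics_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cm <- matrix(as.integer(obj$confusion), 3, 3, byrow = FALSE,
               dimnames = list(true = TLS_CLASS_LABELS,
                               predicted = TLS_CLASS_LABELS))
  cm <- structure(cm, n = sum(cm), class = c("tls_confusion", "matrix"))
  norm <- matrix(as.numeric(obj$normalized), 3, 3,
                 dimnames = dimnames(cm))
  structure(list(confusion = cm, normalized = norm,
                 accuracy = obj$accuracy, kappa = obj$kappa,
                 kappa_band = obj$kappa_band, n = obj$n),
            class = "metrics_report")
}

# Patient-stratified splitting ---------------------------------------------------

#' Exact partition sizes by largest remainder
#'
#' Splits `n` units into `length(ratios)` partitions whose sizes sum to `n`,
#' assigning floor shares first and remaining seats to the largest
#' fractional remainders.
#'
#' @param n number of units.
#' @param ratios non-negative shares summing to 1.
#' @return integer vector of partition sizes.
#' @examples
#' split_sizes(656, c(0.625, 0.172, 0.203))  # 410 113 133
#' @export
split_sizes <- function(n, ratios) {
  if (abs(sum(ratios) - 1) > 1e-6 || any(ratios < 0)) {
    stop("ratios must be non-negative and sum to 1", call. = FALSE)
  }
  raw <- n * ratios
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    top <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

# Per-patient TLS class-count profile matrix (patients x 3).
patient_profiles <- function(tls_table) {
  stopifnot(all(c("patient_id", "true_class") %in% names(tls_table)))
  codes <- class_code(tls_table$true_class)
  tab <- table(tls_table$patient_id, factor(codes, levels = 0:2))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), TLS_CLASS_LABELS))
  m
}

# Greedy class-balanced assignment of patients into groups with fixed patient
# capacities: patients (ordered by descending TLS count, ties in seeded
# shuffled order) go to the group with remaining capacity whose per-class
# TLS counts are furthest below the pro-rata target, followed by a
# deterministic pairwise-swap refinement that descends on the summed squared
# deviation from each group's pro-rata class target.
greedy_assign <- function(profiles, capacities, seed) {
  np <- nrow(profiles)
  ng <- length(capacities)
  stopifnot(sum(capacities) == np)
  totals <- colSums(profiles)
  share <- capacities / np
  targets <- outer(share, totals)
  ord <- with_seed(seed, sample.int(np))
  ord <- ord[order(rowSums(profiles)[ord], decreasing = TRUE)]
  counts <- matrix(0, ng, ncol(profiles))
  sizes <- integer(ng)
  assign_to <- integer(np)
  for (i in ord) {
    open <- which(sizes < capacities)
    dev <- vapply(open, function(g) {
      sum(((counts[g, ] + profiles[i, ]) - targets[g, ])^2)
    }, 0)
    g <- open[which.min(dev)]
    assign_to[i] <- g
    counts[g, ] <- counts[g, ] + profiles[i, ]
    sizes[g] <- sizes[g] + 1L
  }
  refine_assignment(profiles, assign_to, counts, targets)
}

# Steepest-descent swap refinement: repeatedly apply the patient swap (across
# any two groups) that most reduces the squared class-balance deviation;
# group sizes are preserved.  For a swap of patient a (group g1) with b
# (group g2), writing d = profile_b - profile_a and e_g = counts_g -
# target_g, the objective change is 2 d.(e1 - e2) + 2 |d|^2, evaluated for
# all pairs at once.
refine_assignment <- function(profiles, assign_to, counts, targets,
                              max_iter = 500L) {
  ng <- nrow(targets)
  rs <- rowSums(profiles^2)
  for (iter in seq_len(max_iter)) {
    best <- list(delta = -1e-9)
    for (g1 in seq_len(ng - 1L)) for (g2 in (g1 + 1L):ng) {
      i1 <- which(assign_to == g1)
      i2 <- which(assign_to == g2)
      if (!length(i1) || !length(i2)) next
      A <- profiles[i1, , drop = FALSE]
      B <- profiles[i2, , drop = FALSE]
      v <- (counts[g1, ] - targets[g1, ]) - (counts[g2, ] - targets[g2, ])
      delta <- 2 * (outer(-as.vector(A %*% v) + rs[i1],
                          as.vector(B %*% v) + rs[i2], "+") -
                      2 * A %*% t(B))
      m <- which.min(delta)
      if (delta[m] < best$delta) {
        a <- i1[(m - 1L) %% length(i1) + 1L]
        b <- i2[(m - 1L) %/% length(i1) + 1L]
        best <- list(delta = delta[m], a = a, b = b, g1 = g1, g2 = g2)
      }
    }
    if (is.null(best$a)) break
    d <- profiles[best$b, ] - profiles[best$a, ]
    counts[best$g1, ] <- counts[best$g1, ] + d
    counts[best$g2, ] <- counts[best$g2, ] - d
    assign_to[best$a] <- best$g2
    assign_to[best$b] <- best$g1
  }
  assign_to
}

#' Patient-stratified k-fold split with train/validation/test roles
#'
#' Assigns every patient exactly one role per fold, with all of a patient's
#' TLS staying together.  Patients are first divided into `k` class-balanced
#' test groups (each patient is tested in exactly one fold); within each
#' fold the remaining patients are split into train and validation groups at
#' `ratios[1] : ratios[2]`, again balancing per-class TLS proportions.
#' Assignment is deterministic for a fixed seed.  If any class is carried by
#' fewer patients than `k`, exact stratification of that class is infeasible
#' and a warning is issued (assignment still proceeds).
#'
#' @param tls_table data.frame with one row per TLS: `patient_id`,
#'   `true_class` (and anything else, ignored).
#' @param k number of folds (>= 2).
#' @param ratios length-3 shares of (train, validation, test) patients,
#'   summing to 1; the test share is realized by the fold partition, train
#'   and validation by splitting the remainder at `ratios[1]:ratios[2]`.
#' @param seed integer seed.
#' @return object of class `fold_assignment`: data.frame with columns
#'   `fold`, `patient_id`, `role` (train/validation/test).
#' @export
stratified_patient_splits <- function(tls_table, k = 5,
                                      ratios = c(0.625, 0.172, 0.203),
                                      seed = 1) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-6 || any(ratios < 0)) {
    stop("ratios must be 3 non-negative shares summing to 1", call. = FALSE)
  }
  profiles <- patient_profiles(tls_table)
  np <- nrow(profiles)
  if (np < k) stopf("only %d patients for %d folds", np, k)

  carriers <- colSums(profiles > 0)
  thin <- TLS_CLASS_LABELS[carriers > 0 & carriers < k]
  if (length(thin)) {
    warning("stratification infeasible for class(es) with fewer carrier patients than folds: ",
            paste(thin, collapse = ", "),
            "; proceeding with best-effort balanced assignment",
            call. = FALSE)
  }

  fold_caps <- split_sizes(np, rep(1 / k, k))
  fold_of <- greedy_assign(profiles, fold_caps, seed)
  seeds <- derive_seeds(seed, k)

  rows <- vector("list", k)
  tv_ratio <- ratios[1:2] / sum(ratios[1:2])
  for (f in seq_len(k)) {
    test_ids <- rownames(profiles)[fold_of == f]
    rest <- profiles[fold_of != f, , drop = FALSE]
    caps <- split_sizes(nrow(rest), tv_ratio)
    grp <- greedy_assign(rest, caps, seeds[f])
    rows[[f]] <- data.frame(
      fold = f,
      patient_id = c(test_ids, rownames(rest)),
      role = c(rep("test", length(test_ids)),
               c("train", "validation")[grp]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$fold, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fold_assignment", "data.frame")
  out
}

#' Single patient-stratified train/validation/test partition
#'
#' One class-balanced split of patients at the given ratios, with exact
#' partition sizes from [split_sizes()].
#'
#' @inheritParams stratified_patient_splits
#' @return data.frame with columns `patient_id`, `role`.
#' @export
partition_patients <- function(tls_table, ratios = c(0.625, 0.172, 0.203),
                               seed = 1) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-6 || any(ratios < 0)) {
    stop("ratios must be 3 non-negative shares summing to 1", call. = FALSE)
  }
  profiles <- patient_profiles(tls_table)
  caps <- split_sizes(nrow(profiles), ratios)
  grp <- greedy_assign(profiles, caps, seed)
  data.frame(patient_id = rownames(profiles),
             role = c("train", "validation", "test")[grp],
             stringsAsFactors = FALSE)
}

#' Write a fold assignment as CSV
#'
#' @param assignment a [stratified_patient_splits()] result.
#' @param path CSV path.
#' @export
write_fold_assignment <- function(assignment, path) {
  utils::write.csv(as.data.frame(assignment), path, row.names = FALSE)
  invisible(path)
}

# Cross-validation ----------------------------------------------------------------

#' Patient-stratified cross-validated evaluation
#'
#' Runs `k` training runs on a tile manifest: for each fold, the classifier
#' is trained on the fold's training patients, and evaluated on the fold's
#' validation patients at tile level and -- after aggregating tile
#' predictions per TLS under each requested method -- at TLS level (every
#' TLS weighted equally regardless of tile count).  All folds are reported
#' symmetrically.
#'
#' @param manifest tile manifest with `tile_id`, `tls_id`, `patient_id`,
#'   `true_class` and pixels or `tile_path`.
#' @param config a [training_config()]; its seed also drives the split.
#' @param methods aggregation methods to evaluate.
#' @param k number of folds.
#' @param ratios patient shares of (train, validation, test).
#' @return data.frame keyed by (`fold`, `level`, `method`): `accuracy`,
#'   `kappa`, `kappa_band`, `n`; attribute `folds` carries the
#'   fold assignment and `models` the fitted classifiers.
#' @export
crossval_report <- function(manifest, config = training_config(),
                            methods = AGGREGATION_METHODS, k = 5,
                            ratios = c(0.625, 0.172, 0.203)) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  folds <- stratified_patient_splits(manifest, k = k, ratios = ratios,
                                     seed = config$seed)
  rows <- list()
  models <- vector("list", k)
  for (f in seq_len(k)) {
    fa <- folds[folds$fold == f, ]
    role_of <- stats::setNames(fa$role, fa$patient_id)
    tr <- manifest[role_of[manifest$patient_id] == "train", , drop = FALSE]
    va <- manifest[role_of[manifest$patient_id] == "validation", , drop = FALSE]
    model <- train_classifier(tr, va, config)
    models[[f]] <- model
    preds <- predict_tiles(model, va)
    preds$tls_id <- va$tls_id

    tile_m <- metrics_report(va$true_class, preds$pred_class)
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, level = "tile", method = NA_character_,
      accuracy = tile_m$accuracy, kappa = tile_m$kappa,
      kappa_band = tile_m$kappa_band, n = tile_m$n,
      stringsAsFactors = FALSE)

    tls_truth <- unique(va[, c("tls_id", "true_class")])
    agg <- aggregate_all(preds, methods)
    for (m in methods) {
      am <- agg[agg$method == m, ]
      am <- am[match(tls_truth$tls_id, am$tls_id), ]
      mm <- metrics_report(tls_truth$true_class, am$pred_class)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, level = "tls", method = m, accuracy = mm$accuracy,
        kappa = mm$kappa, kappa_band = mm$kappa_band, n = mm$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  attr(out, "models") <- models
  out
}
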