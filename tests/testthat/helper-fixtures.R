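# Shared fixture builders.  All fixtures are generated in code; nothing is
# stored on disk.

# Tile-prediction frame with near-one-hot probabilities for given labels.
pred_frame <- function(labels, conf = 0.9, tls_id = NULL) {
  n <- length(labels)
  P <- matrix((1 - conf) / 2, n, 3)
  P[cbind(seq_len(n), labels + 1L)] <- conf
  out <- data.frame(tile_id = sprintf("t%03d", seq_len(n)),
                    p_aggregate = P[, 1], p_nongc = P[, 2], p_gc = P[, 3],
                    pred_class = labels, confidence = rep(conf, n),
                    stringsAsFactors = FALSE)
  if (!is.null(tls_id)) out$tls_id <- tls_id
  out
}

# In-memory manifest of generated tiles, n_per tiles per class.
tile_manifest <- function(n_per, seed0, size = 56, patient_prefix = "P") {
  cls <- rep(0:2, each = n_per)
  pix <- lapply(seq_along(cls),
                function(i) generate_tile(cls[i], seed = seed0 + i, size = size))
  out <- data.frame(tile_id = sprintf("%s_t%05d", patient_prefix,
                                      seed0 + seq_along(cls)),
                    true_class = cls,
                    patient_id = sprintf("%s%02d", patient_prefix,
                                         seq_along(cls) %% 7L),
                    stringsAsFactors = FALSE)
  out$pixels <- pix
  out
}

# Axis-aligned rectangle polygon (x0, y0) -- (x0+w, y0+h).
rect_poly <- function(x0, y0, w, h) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

square_annotation <- function(x0, y0, side, id = "T1") {
  tls_annotation(id, "S1", "P1", rect_poly(x0, y0, side, side), 0)
}

# --- independent brute-force oracles -----------------------------------------

# Tie rule used across oracles: ties resolve toward the more mature class.
oracle_argmax <- function(x) max(which(x == max(x))) - 1L

# Naive re-implementation of each aggregation rule, written directly from
# the definitions, independent of the package's code path.
oracle_aggregate <- function(method, labels, P = NULL, conf = NULL) {
  if (method %in% c("majority", "mode")) {
    cnt <- c(sum(labels == 0), sum(labels == 1), sum(labels == 2))
    return(oracle_argmax(cnt))
  }
  if (method == "average") {
    m <- sum(labels) / length(labels)
    return(floor(m + 0.5))
  }
  if (method == "median") {
    s <- sort(labels)
    n <- length(s)
    med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    return(floor(med + 0.5))
  }
  if (method == "custom") {
    if (any(labels == 2)) return(2L)
    if (any(labels == 1)) return(1L)
    return(0L)
  }
  if (method == "soft_voting") {
    return(oracle_argmax(c(mean(P[, 1]), mean(P[, 2]), mean(P[, 3]))))
  }
  if (method == "max_confidence") {
    best <- which(conf == max(conf))
    return(max(labels[best]))
  }
  stop("unknown method in oracle")
}

# All probability vectors on a 5-point grid {0, .25, .5, .75, 1} summing to 1.
prob_grid_5 <- function() {
  g <- seq(0, 1, by = 0.25)
  out <- list()
  for (a in g) for (b in g) {
    if (a + b <= 1) out[[length(out) + 1L]] <- c(a, b, 1 - a - b)
  }
  do.call(rbind, out)
}
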