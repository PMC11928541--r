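test_that("aggregation follows each method's definition on the documented cases", {
  # maturity priority: any GC tile makes the TLS GC
  expect_identical(aggregate_tls(pred_frame(c(0, 0, 2)), "custom")$pred_class, 2L)
  # while majority counts 2 vs 1
  expect_identical(aggregate_tls(pred_frame(c(0, 0, 2)), "majority")$pred_class, 0L)
  # max confidence picks the single most confident tile
  mc <- data.frame(p_aggregate = c(0.6, 0.1), p_nongc = c(0.3, 0.1),
                   p_gc = c(0.1, 0.8))
  expect_identical(aggregate_tls(mc, "max_confidence")$pred_class, 2L)
  # ordinal mean / median
  expect_identical(aggregate_tls(pred_frame(c(0, 1, 2)), "average")$pred_class, 1L)
  expect_identical(aggregate_tls(pred_frame(c(0, 2)), "median")$pred_class, 1L)
  # constructed soft-voting tie resolves toward the more mature class
  sv <- data.frame(p_aggregate = c(0.6, 0.2), p_nongc = c(0.3, 0.5),
                   p_gc = c(0.1, 0.3))
  r <- aggregate_tls(sv, "soft_voting")
  expect_identical(r$pred_class, 1L)
  expect_true(r$tie_broken)

  expect_error(aggregate_tls(pred_frame(integer(0)), "custom"), "empty")
  expect_error(aggregate_tls(pred_frame(0L), "plurality"), "unknown aggregation")
})

test_that("every method matches brute-force enumeration for all label tuples up to size 4", {
  tuples <- unlist(lapply(1:4, function(n) {
    g <- do.call(expand.grid, rep(list(0:2), n))
    lapply(seq_len(nrow(g)), function(i) as.integer(unlist(g[i, ])))
  }), recursive = FALSE)
  expect_length(tuples, 3 + 9 + 27 + 81)
  for (labels in tuples) {
    pf <- pred_frame(labels)
    P <- as.matrix(pf[, c("p_aggregate", "p_nongc", "p_gc")])
    for (m in AGGREGATION_METHODS) {
      want <- oracle_aggregate(m, labels, P = P, conf = pf$confidence)
      got <- aggregate_tls(pf, m)$pred_class
      expect_identical(got, as.integer(want),
                       label = sprintf("%s on (%s)", m,
                                       paste(labels, collapse = ",")))
    }
  }
})

test_that("soft voting and max confidence match enumeration on a 5-point probability grid", {
  G <- prob_grid_5()
  idx <- expand.grid(i = seq_len(nrow(G)), j = seq_len(nrow(G)))
  for (r in seq_len(nrow(idx))) {
    P <- G[c(idx$i[r], idx$j[r]), , drop = FALSE]
    pf <- data.frame(p_aggregate = P[, 1], p_nongc = P[, 2], p_gc = P[, 3])
    labels <- apply(P, 1, oracle_argmax)
    conf <- apply(P, 1, max)
    for (m in c("soft_voting", "max_confidence")) {
      want <- oracle_aggregate(m, labels, P = P, conf = conf)
      expect_identical(aggregate_tls(pf, m)$pred_class, as.integer(want),
                       label = sprintf("%s grid pair %d", m, r))
    }
  }
})

test_that("aggregation is permutation-invariant and unanimous", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    P <- matrix(runif(3 * n), n)
    P <- P / rowSums(P)
    pf <- data.frame(p_aggregate = P[, 1], p_nongc = P[, 2], p_gc = P[, 3])
    perm <- sample(n)
    for (m in AGGREGATION_METHODS) {
      expect_identical(aggregate_tls(pf, m)$pred_class,
                       aggregate_tls(pf[perm, ], m)$pred_class,
                       label = paste("permutation invariance:", m))
    }
  }
  for (c in 0:2) {
    pf <- pred_frame(rep(c, 5))
    for (m in AGGREGATION_METHODS) {
      expect_identical(aggregate_tls(pf, m)$pred_class, c,
                       label = paste("unanimity:", m))
    }
  }
})

test_that("the custom rule dominates every method and is monotone in maturity", {
  set.seed(77)
  for (rep in 1:50) {
    labels <- sample(0:2, sample(1:10, 1), replace = TRUE)
    pf <- pred_frame(labels)
    cust <- aggregate_tls(pf, "custom")$pred_class
    expect_identical(cust, max(labels))
    for (m in AGGREGATION_METHODS) {
      expect_lte(aggregate_tls(pf, m)$pred_class, cust)
    }
    # raising one tile's label never lowers the custom output
    i <- sample(seq_along(labels), 1)
    raised <- labels
    raised[i] <- min(2L, raised[i] + 1L)
    expect_gte(aggregate_tls(pred_frame(raised), "custom")$pred_class, cust)
  }
})

test_that("aggregate_all produces one row per TLS per method, deterministically", {
  pf <- rbind(pred_frame(c(0, 0, 1), tls_id = "A"),
              pred_frame(c(2, 2), tls_id = "B"))
  pf$tile_id <- sprintf("t%d", seq_len(nrow(pf)))
  out <- aggregate_all(pf)
  expect_identical(nrow(out), 2L * 7L)
  expect_identical(out, aggregate_all(pf))
  # single-tile TLS: all methods return its label
  single <- pred_frame(2L, tls_id = "C")
  res <- aggregate_all(single)
  expect_true(all(res$pred_class == 2L))
  expect_true(all(res$support == 1L))
  # duplicate tile ids are an integrity error
  dup <- pf
  dup$tile_id[2] <- dup$tile_id[1]
  expect_error(aggregate_all(dup), "duplicate tile_id")
})

test_that("the custom rule's error amplification matches its closed form", {
  expect_equal(custom_error_curve(0, 15), 0)
  expect_equal(custom_error_curve(0.05, 15), 1 - 0.95^15)
  # strictly increasing in the number of tiles
  curve <- custom_error_curve(0.05, 1:40)
  expect_true(all(diff(curve) > 0))
  # Monte-Carlo agreement within 3 binomial SE
  mc <- custom_error_mc(0.05, 15, reps = 3000, seed = 21)
  truth <- custom_error_curve(0.05, 15)
  expect_lt(abs(mc$estimate - truth), 3 * sqrt(truth * (1 - truth) / 3000))
  expect_error(custom_error_curve(1.2, 5), "epsilon")
})
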