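test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion_matrix(c(0, 1, 2), c(0, 1, 2))
  expect_identical(unname(diag(unclass(cm))), c(1L, 1L, 1L))
  expect_identical(sum(cm), 3L)

  cm2 <- confusion_matrix(c(2, 2), c(0, 0))
  expect_identical(unclass(cm2)[3, 1], 2L)
  expect_identical(sum(unclass(cm2)) - unclass(cm2)[3, 1], 0L)

  set.seed(4)
  cm3 <- confusion_matrix(sample(0:2, 1000, TRUE), sample(0:2, 1000, TRUE))
  expect_identical(sum(cm3), 1000L)

  expect_error(confusion_matrix(0:1, 0:2), "length mismatch")
})

test_that("row normalization yields per-true-class percentages", {
  cm <- confusion_matrix(rep(0, 4), c(0, 1, 2, 2))
  m <- normalize_confusion(cm)
  expect_equal(unname(m[1, ]), c(25, 25, 50))
  expect_true(all(is.na(m[2:3, ])))  # zero-support rows undefined, not 0

  ident <- confusion_matrix(0:2, 0:2)
  expect_equal(unname(diag(normalize_confusion(ident))), c(100, 100, 100))

  set.seed(9)
  cm3 <- confusion_matrix(sample(0:2, 500, TRUE), sample(0:2, 500, TRUE))
  expect_true(all(abs(rowSums(normalize_confusion(cm3)) - 100) < 0.01))
  # column normalization sums predicted-class columns to 100
  expect_true(all(abs(colSums(normalize_confusion(cm3, by = "pred")) - 100) < 0.01))
})

test_that("Cohen's kappa matches hand computation and its agreement bands", {
  perfect <- confusion_matrix(rep(0:2, each = 10), rep(0:2, each = 10))
  k <- cohens_kappa(perfect)
  expect_equal(k$kappa, 1)
  expect_identical(k$band, "almost_perfect")

  # hand-computable matrix: p_o = 11/15, p_e = 1/3, kappa = 0.6
  hand <- matrix(c(4, 1, 0, 1, 3, 1, 0, 1, 4), 3, byrow = TRUE)
  k2 <- cohens_kappa(hand)
  expect_equal(k2$kappa, 0.6)
  expect_equal(k2$p_o, 11 / 15)
  expect_equal(k2$p_e, 1 / 3)
  expect_identical(k2$band, "moderate")
  expect_equal(accuracy(hand), 11 / 15)

  # band cutpoints (half-open at the lower edge)
  expect_identical(kappa_band(c(0.1, 0.20, 0.3, 0.40, 0.5, 0.60, 0.7, 0.80, 0.9)),
                   c("minimal", "minimal", "fair", "fair", "moderate",
                     "moderate", "substantial", "substantial", "almost_perfect"))

  # degenerate single-category agreement: undefined, not NaN
  degen <- confusion_matrix(rep(0, 5), rep(0, 5))
  kd <- cohens_kappa(degen)
  expect_true(is.na(kd$kappa))
  expect_identical(kd$band, "undefined")
})

test_that("kappa vanishes for independent raters and matches an external implementation", {
  set.seed(123)
  a <- sample(0:2, 10000, TRUE)
  b <- sample(0:2, 10000, TRUE)
  k <- cohens_kappa(confusion_matrix(a, b))$kappa
  expect_lt(abs(k), 0.05)

  skip_if_not_installed("e1071")
  for (i in 1:5) {
    x <- sample(0:2, 200, TRUE)
    y <- ifelse(runif(200) < 0.6, x, sample(0:2, 200, TRUE))
    ours <- cohens_kappa(confusion_matrix(x, y))$kappa
    ref <- e1071::classAgreement(table(x, y))$kappa
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("kappa is invariant to a simultaneous class permutation", {
  set.seed(5)
  x <- sample(0:2, 300, TRUE)
  y <- sample(0:2, 300, TRUE)
  perm <- c(2L, 0L, 1L)
  k1 <- cohens_kappa(confusion_matrix(x, y))$kappa
  k2 <- cohens_kappa(confusion_matrix(perm[x + 1L], perm[y + 1L]))$kappa
  expect_equal(k1, k2)
})

test_that("largest-remainder sizes reproduce the cohort partition", {
  expect_identical(split_sizes(656, c(0.625, 0.172, 0.203)),
                   c(410L, 113L, 133L))
  expect_identical(sum(split_sizes(97, c(1, 1, 1) / 3)), 97L)
  expect_error(split_sizes(10, c(0.5, 0.6)), "sum to 1")
})

test_that("stratified splits are patient-exclusive, balanced and deterministic", {
  cohort <- generate_cohort(100, mean_tls_per_patient = 6, seed = 2)
  fa <- stratified_patient_splits(cohort, k = 5, seed = 3)

  # each patient has exactly one role per fold, and is tested exactly once
  expect_true(all(table(fa$patient_id, fa$fold) == 1L))
  tested <- table(fa$patient_id[fa$role == "test"])
  expect_identical(length(tested), 100L)
  expect_true(all(tested == 1L))

  # per-class TLS proportions within 5 points of global, in every partition
  glob <- prop.table(table(factor(cohort$true_class, 0:2)))
  for (f in 1:5) {
    roles <- fa[fa$fold == f, ]
    merged <- merge(cohort, roles, by = "patient_id")
    for (r in c("train", "validation", "test")) {
      part <- merged[merged$role == r, ]
      prop <- prop.table(table(factor(part$true_class, 0:2)))
      expect_lt(max(abs(prop - glob)), 0.05,
                label = sprintf("fold %d %s class balance", f, r))
    }
  }

  expect_identical(fa, stratified_patient_splits(cohort, k = 5, seed = 3))
  expect_false(identical(fa, stratified_patient_splits(cohort, k = 5, seed = 4)))
})

test_that("single partitions honor exact sizes, and thin classes degrade gracefully", {
  cohort <- generate_cohort(40, mean_tls_per_patient = 5, seed = 7)
  roles <- partition_patients(cohort, c(0.625, 0.172, 0.203), seed = 1)
  expect_identical(
    as.integer(table(roles$role)[c("train", "validation", "test")]),
    split_sizes(40, c(0.625, 0.172, 0.203)))

  # one class carried by a single patient: stratification infeasible warning
  rare <- cohort
  rare$true_class[rare$true_class == 1L] <- 0L
  rare$true_class[rare$patient_id == "P001"] <- 1L
  expect_warning(stratified_patient_splits(rare, k = 5, seed = 1),
                 "stratification infeasible.*Non-GC")
})

test_that("cross-validation reports per-fold tile and TLS metrics that serialize", {
  spec <- synthetic_slide_spec(n_tls = 48, seed = 19, mean_tiles_per_tls = 6,
                               tile_size = 48, n_patients = 12)
  sl <- generate_slide(spec)
  tiles <- extract_all_tiles(sl$image, sl$annotations, tile_size = 48)
  rep <- crossval_report(tiles, training_config(epochs = 8, seed = 6),
                         methods = c("max_confidence", "custom"), k = 2,
                         ratios = c(0.6, 0.2, 0.2))
  expect_identical(nrow(rep), 2L * (1L + 2L))  # per fold: tile + 2 methods
  expect_identical(sum(rep$level == "tile"), 2L)
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
  expect_gte(min(rep$accuracy[rep$level == "tile"]), 0.9)

  # metrics JSON round-trip
  m <- metrics_report(c(0, 1, 2, 2), c(0, 1, 2, 1))
  path <- tempfile(fileext = ".json")
  write_metrics_json(m, path)
  m2 <- read_metrics_json(path)
  expect_equal(m2$accuracy, m$accuracy)
  expect_equal(m2$kappa, m$kappa)
  expect_identical(m2$kappa_band, m$kappa_band)
  expect_equal(unclass(m2$confusion), unclass(m$confusion),
               ignore_attr = TRUE)
  expect_equal(m2$normalized, m$normalized, ignore_attr = TRUE)
})
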