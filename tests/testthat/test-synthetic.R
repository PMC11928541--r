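test_that("generated tiles carry their class-defining stain signals", {
  agg <- generate_tile("Aggregate", stain_params(), seed = 1)
  f <- stain_fractions(agg)
  expect_lt(f[["red"]], 0.01)
  expect_lt(f[["dab"]], 0.01)

  gc <- generate_tile("GC", stain_params(), seed = 1)
  f <- stain_fractions(gc)
  expect_gte(f[["red"]], 0.05)
  expect_gte(f[["dab"]], 0.02)

  ngc <- generate_tile("Non-GC", stain_params(), seed = 3)
  f <- stain_fractions(ngc)
  expect_gte(f[["red"]], 0.05)
  expect_lt(f[["dab"]], 0.02)

  expect_error(generate_tile("Germinal"), "unknown maturation class")
})

test_that("tile generation is bit-identical under a fixed seed", {
  a <- generate_tile("Non-GC", seed = 7)
  b <- generate_tile("Non-GC", seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_tile("Non-GC", seed = 8)))
})

test_that("a fixed stain-dominance classifier separates generated classes", {
  set.seed(42)
  cls <- sample(0:2, 300, replace = TRUE)
  pred <- vapply(seq_along(cls), function(i) {
    classify_tile_by_stain(generate_tile(cls[i], seed = 1000 + i, size = 56))
  }, 0L)
  expect_gte(mean(pred == cls), 0.99)
})

test_that("degenerate class mix yields a single class and slides are reproducible", {
  spec <- synthetic_slide_spec(n_tls = 3, class_mix = c(1, 0, 0), seed = 2,
                               mean_tiles_per_tls = 4, tile_size = 48)
  sl <- generate_slide(spec)
  expect_length(sl$annotations, 3L)
  expect_true(all(sl$truth$true_class == 0L))
  sl2 <- generate_slide(spec)
  expect_identical(sl$image, sl2$image)
  expect_identical(sl$truth, sl2$truth)
})

test_that("slide class frequencies converge to the specified mix", {
  mix <- c(0.333, 0.162, 0.505)
  spec <- synthetic_slide_spec(n_tls = 3000, class_mix = mix, seed = 5,
                               mean_tiles_per_tls = 4, tile_size = 32)
  sl <- generate_slide(spec, render = FALSE)
  counts <- tabulate(sl$truth$true_class + 1L, 3L)
  for (c in 1:3) {
    se <- sqrt(mix[c] * (1 - mix[c]) / 3000)
    expect_lt(abs(counts[c] / 3000 - mix[c]), 3 * se)
  }
})

test_that("slide class counts fall inside binomial 99% bounds at n = 300", {
  mix <- c(0.333, 0.162, 0.505)
  spec <- synthetic_slide_spec(n_tls = 300, class_mix = mix, seed = 5,
                               mean_tiles_per_tls = 4, tile_size = 32)
  sl <- generate_slide(spec, render = FALSE)
  counts <- tabulate(sl$truth$true_class + 1L, 3L)
  for (c in 1:3) {
    expect_gte(counts[c], qbinom(0.005, 300, mix[c]))
    expect_lte(counts[c], qbinom(0.995, 300, mix[c]))
  }
})

test_that("slide polygons are disjoint, in-canvas, and placement failures are explicit", {
  spec <- synthetic_slide_spec(n_tls = 12, seed = 4, mean_tiles_per_tls = 5,
                               tile_size = 48, n_patients = 4)
  sl <- generate_slide(spec, render = FALSE)
  polys <- lapply(sl$annotations, `[[`, "polygon")
  bbs <- lapply(polys, function(p) c(min(p[, 1]), min(p[, 2]),
                                     max(p[, 1]), max(p[, 2])))
  for (i in seq_along(bbs)) {
    for (j in seq_len(i - 1L)) {
      a <- bbs[[i]]; b <- bbs[[j]]
      disjoint <- a[3] < b[1] || b[3] < a[1] || a[4] < b[2] || b[4] < a[2]
      expect_true(disjoint, label = sprintf("bboxes %d and %d disjoint", i, j))
    }
  }
  expect_error(
    generate_slide(synthetic_slide_spec(n_tls = 50, canvas_size = c(400, 400),
                                        tile_size = 48), render = FALSE),
    "placement failure")
})

test_that("corrupted predictions honor the error rate and kernel", {
  # zero-noise identity
  p0 <- corrupt_predictions(c(0, 1, 2, 0), epsilon = 0, seed = 1)
  expect_identical(p0$pred_class, c(0L, 1L, 2L, 0L))
  expect_true(all(abs(p0$p_aggregate + p0$p_nongc + p0$p_gc - 1) < 1e-9))

  # saturation: all mass Aggregate -> GC
  k <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, byrow = TRUE)
  p1 <- corrupt_predictions(rep(0L, 50), epsilon = 1, confusion_kernel = k,
                            seed = 2)
  expect_true(all(p1$pred_class == 2L))

  # binomial oracle: flipped fraction within 3 SE of epsilon
  p <- corrupt_predictions(rep(0L, 10000), epsilon = 0.05, seed = 3)
  flipped <- mean(p$pred_class != 0L)
  expect_lt(abs(flipped - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))

  # reproducibility and kernel validation
  expect_identical(corrupt_predictions(rep(0:2, 10), 0.3, seed = 9),
                   corrupt_predictions(rep(0:2, 10), 0.3, seed = 9))
  bad <- matrix(c(0.5, 0.5, 0.5, 0, 0, 1, 0, 0, 1), 3, byrow = TRUE)
  expect_error(corrupt_predictions(0L, 0.1, confusion_kernel = bad),
               "row-stochastic")
})

test_that("stain parameter invariants are enforced", {
  expect_error(stain_params(intensity_jitter = 1.2), "intensity_jitter")
  expect_error(stain_params(artifact_rate = -0.1), "artifact_rate")
  expect_error(stain_params(red_rgb = c(2, 0, 0)), "RGB")
  expect_error(synthetic_slide_spec(class_mix = c(0.5, 0.5, 0.5)), "class_mix")
  expect_error(synthetic_slide_spec(n_tls = 0), "n_tls")
})
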