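test_that("axis-aligned squares tile exactly", {
  one <- extract_tiles(NULL, square_annotation(10, 20, 224))
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$x0, one$y0), c(10L, 20L))

  four <- extract_tiles(NULL, square_annotation(0, 0, 448))
  expect_identical(nrow(four), 4L)
  # row-major ordering over the 2x2 grid
  expect_identical(four$grid_row, c(0L, 0L, 1L, 1L))
  expect_identical(four$grid_col, c(0L, 1L, 0L, 1L))
})

test_that("tile retention matches a brute-force point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(99)
  ts <- 64L
  for (rep in 1:12) {
    r <- runif(1, 40, 140)
    blob <- tlsmat:::new_blob(cx = runif(1, 200, 300), cy = runif(1, 200, 300),
                              r = r)
    poly <- tlsmat:::blob_polygon(blob, m = 36)
    ann <- tls_annotation("T", "S", "P", poly, 0)
    got <- extract_tiles(NULL, ann, tile_size = ts)

    # oracle: classify every pixel center in the grid bounding box
    bb <- tlsmat:::polygon_bbox(poly)
    ax <- floor(bb["xmin"]); ay <- floor(bb["ymin"])
    nc <- max(1, ceiling((bb["xmax"] - ax) / ts))
    nr <- max(1, ceiling((bb["ymax"] - ay) / ts))
    px <- as.vector(outer(rep(1, nr * ts), ax + seq_len(nc * ts) - 0.5))
    py <- as.vector(outer(ay + seq_len(nr * ts) - 0.5, rep(1, nc * ts)))
    inside <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py))
    cellr <- (rep(seq_len(nr * ts), nc * ts) - 1) %/% ts
    cellc <- (rep(seq_len(nc * ts), each = nr * ts) - 1) %/% ts
    cnt <- tapply(inside, list(cellr, cellc), sum)
    want <- which(t(cnt) >= 0.5 * ts^2)  # row-major
    expect_identical(nrow(got), length(want),
                     label = sprintf("rep %d tile count", rep))
    # per-cell agreement
    got_cells <- sort(as.integer(got$grid_row * nc + got$grid_col))
    oracle_cells <- sort(as.integer(want - 1L))
    expect_identical(got_cells, oracle_cells)
  }
})

test_that("tiles never overlap and honor the overlap-fraction rule", {
  set.seed(7)
  blob <- tlsmat:::new_blob(cx = 400, cy = 380, r = 200)
  poly <- tlsmat:::blob_polygon(blob, m = 48)
  ann <- tls_annotation("T", "S", "P", poly, 1)
  tiles <- extract_tiles(NULL, ann, tile_size = 96)
  expect_gt(nrow(tiles), 3L)
  # non-overlap: grid cells are unique
  expect_false(anyDuplicated(tiles[, c("x0", "y0")]) > 0)
  # containment: recompute each tile's covered-pixel fraction independently
  skip_if_not_installed("mgcv")
  for (i in seq_len(nrow(tiles))) {
    px <- rep(tiles$x0[i] + seq_len(96) - 0.5, each = 96)
    py <- rep(tiles$y0[i] + seq_len(96) - 0.5, times = 96)
    frac <- mean(mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py)))
    expect_gte(frac, 0.5)
    expect_equal(frac, tiles$overlap_fraction[i], tolerance = 1e-8)
  }
  # min_overlap_fraction = 0 keeps strictly more (boundary) tiles
  tiles0 <- extract_tiles(NULL, ann, tile_size = 96, min_overlap_fraction = 0)
  expect_gt(nrow(tiles0), nrow(tiles))
})

test_that("a polygon smaller than the overlap threshold yields zero tiles with a warning", {
  small <- square_annotation(5, 5, 50)
  expect_warning(t0 <- extract_tiles(NULL, small, tile_size = 224),
                 "no tiles extracted")
  expect_identical(nrow(t0), 0L)
})

test_that("extraction is idempotent and slide pixels match tile pixels", {
  spec <- synthetic_slide_spec(n_tls = 4, seed = 21, mean_tiles_per_tls = 5,
                               tile_size = 48, n_patients = 2)
  sl <- generate_slide(spec)
  t1 <- extract_all_tiles(sl$image, sl$annotations, tile_size = 48)
  t2 <- extract_all_tiles(sl$image, sl$annotations, tile_size = 48)
  expect_identical(t1, t2)
  i <- which.max(t1$overlap_fraction)
  expect_identical(t1$pixels[[i]],
                   sl$image[(t1$y0[i] + 1):(t1$y0[i] + 48),
                            (t1$x0[i] + 1):(t1$x0[i] + 48), , drop = FALSE])
})

test_that("overview images have scaled dimensions and show every tile", {
  spec <- synthetic_slide_spec(n_tls = 4, seed = 13, mean_tiles_per_tls = 5,
                               tile_size = 48, n_patients = 2)
  sl <- generate_slide(spec)
  tiles <- extract_all_tiles(sl$image, sl$annotations, tile_size = 48)

  # scale 1 with zero tiles: unmodified copy
  same <- render_overview(sl$image, tiles[0, ], scale_factor = 1)
  expect_identical(same, sl$image)

  ov <- render_overview(sl$image, tiles, scale_factor = 0.1, tile_size = 48)
  expect_identical(dim(ov)[1:2],
                   as.integer(ceiling(dim(sl$image)[1:2] * 0.1)))
  # every tile paints at least its own outline pixels green
  greens <- ov[, , 2] > 0.85 & ov[, , 1] < 0.2
  expect_gte(sum(greens), nrow(tiles) * 4L)

  expect_error(render_overview(sl$image, tiles, scale_factor = 0), "scale_factor")
})

test_that("manifests round-trip and enforce referential integrity", {
  spec <- synthetic_slide_spec(n_tls = 5, seed = 31, mean_tiles_per_tls = 5,
                               tile_size = 48, n_patients = 2)
  sl <- generate_slide(spec, render = FALSE)
  tiles <- extract_all_tiles(NULL, sl$annotations, tile_size = 48)
  path <- tempfile(fileext = ".csv")
  m <- write_manifest(tiles, sl$annotations, path, tile_size = 48)
  m2 <- read_manifest(path)
  expect_equal(m, m2, ignore_attr = TRUE)
  expect_identical(nrow(m), nrow(tiles))
  # one row per tile, with its TLS identity preserved
  expect_setequal(unique(m$tls_id), sl$truth$tls_id)

  orphan <- tiles
  orphan$tls_id[1] <- "TLS_9999"
  expect_error(write_manifest(orphan, sl$annotations, path),
               "referential-integrity")
})

test_that("manifest tile totals track the mean tiles-per-TLS of the generator", {
  spec <- synthetic_slide_spec(n_tls = 300, seed = 17, mean_tiles_per_tls = 15,
                               tile_size = 56, n_patients = 30)
  sl <- generate_slide(spec, render = FALSE)
  tiles <- extract_all_tiles(NULL, sl$annotations, tile_size = 56)
  # Poisson oracle: total tile count within 3 SE of n_tls * mean
  expect_lt(abs(nrow(tiles) - 300 * 15), 3 * sqrt(300 * 15))
})
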