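#' Stain rendering parameters for the synthetic dual-IHC generator
#'
#' Controls the appearance of synthetic dual CD21/CD23 immunohistochemistry:
#' a hematoxylin-like background, CD21 follicular-dendritic-cell meshwork in
#' red chromogen, and CD23 germinal-center signal in brown DAB.
#'
#' @param background_rgb hematoxylin counterstain color (RGB in `[0,1]`).
#' @param red_rgb CD21 red-chromogen color.
#' @param dab_rgb CD23 DAB (brown) color.
#' @param intensity_jitter multiplicative stain-intensity noise half-range;
#'   each rendered structure's stain color is scaled by a factor drawn
#'   uniformly from `1 +/- intensity_jitter`.  Must lie in `[0, 1)`.
#' @param artifact_rate probability per tile (or per TLS on a slide) of an
#'   occluding gray artifact blob, in `[0, 1]`.
#' @param noise_sd additive Gaussian pixel noise standard deviation on the
#'   0--255 scale.
#' @return an object of class `stain_params` (a validated list).
#' @export
stain_params <- function(background_rgb = c(0.82, 0.80, 0.90),
                         red_rgb = c(0.76, 0.12, 0.18),
                         dab_rgb = c(0.45, 0.28, 0.12),
                         intensity_jitter = 0.3,
                         artifact_rate = 0.05,
                         noise_sd = 6) {
  if (!is_rgb_color(background_rgb) || !is_rgb_color(red_rgb) ||
      !is_rgb_color(dab_rgb)) {
    stop("stain colors must be RGB triples in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(intensity_jitter) || length(intensity_jitter) != 1L ||
      intensity_jitter < 0 || intensity_jitter >= 1) {
    stop("intensity_jitter must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(artifact_rate) || length(artifact_rate) != 1L ||
      artifact_rate < 0 || artifact_rate > 1) {
    stop("artifact_rate must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("noise_sd must be a non-negative number (0-255 scale)", call. = FALSE)
  }
  structure(list(background_rgb = background_rgb, red_rgb = red_rgb,
                 dab_rgb = dab_rgb, intensity_jitter = intensity_jitter,
                 artifact_rate = artifact_rate, noise_sd = noise_sd),
            class = "stain_params")
}

#' Specification of a synthetic slide
#'
#' Describes a synthetic whole-slide image carrying `n_tls` disjoint TLS
#' footprints with known maturation classes.  Defaults mirror the study
#' conditions: 224-pixel tiles, a mean of 15 tiles per TLS, and a
#' class mix of 0.333 / 0.162 / 0.505 (Aggregate / Non-GC / GC) matching the
#' tile imbalance of the annotated cohort (33,399 / 16,242 / 50,604 tiles).
#'
#' @param n_tls number of TLS to place (>= 1).
#' @param class_mix probabilities of (Aggregate, Non-GC, GC); must sum to 1.
#' @param mean_tiles_per_tls expected number of retained 224x224 tiles per
#'   TLS; footprint areas are sized as `n_i * tile_size^2` with
#'   `n_i ~ 1 + Poisson(mean - 1)`.
#' @param seed integer seed; drives a hierarchical per-TLS seed derivation.
#' @param canvas_size `c(width, height)` in pixels, or `NULL` to size the
#'   canvas automatically to hold `n_tls` disjoint footprints.
#' @param tile_size tile side in pixels used to scale footprints (default
#'   224; smaller values give desk-scale slides).
#' @param n_patients number of synthetic patients the TLS are spread over.
#' @param slide_id identifier recorded in annotations and truth table.
#' @return an object of class `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(n_tls = 10, class_mix = c(0.333, 0.162, 0.505),
                                 mean_tiles_per_tls = 15, seed = 1,
                                 canvas_size = NULL, tile_size = 224,
                                 n_patients = 1, slide_id = "S1") {
  if (!is.numeric(n_tls) || length(n_tls) != 1L || n_tls < 1) {
    stop("n_tls must be >= 1", call. = FALSE)
  }
  if (!is.numeric(class_mix) || length(class_mix) != 3L || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-6) {
    stop("class_mix must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (mean_tiles_per_tls < 1) stop("mean_tiles_per_tls must be >= 1", call. = FALSE)
  if (tile_size < 8) stop("tile_size must be >= 8 pixels", call. = FALSE)
  if (!is.null(canvas_size) && (length(canvas_size) != 2L || any(canvas_size <= 0))) {
    stop("canvas_size must be c(width, height) in pixels", call. = FALSE)
  }
  structure(list(n_tls = as.integer(n_tls), class_mix = class_mix,
                 mean_tiles_per_tls = mean_tiles_per_tls,
                 seed = as.integer(seed), canvas_size = canvas_size,
                 tile_size = as.integer(tile_size),
                 n_patients = as.integer(n_patients), slide_id = slide_id),
            class = "synthetic_slide_spec")
}

# ---- internal rendering primitives -----------------------------------------

# Pixel-center coordinate grids for a h x w window whose top-left pixel has
# 0-based coordinates (x_off, y_off).
pixel_grids <- function(h, w, x_off = 0, y_off = 0) {
  list(X = matrix(x_off + seq_len(w) - 0.5, h, w, byrow = TRUE),
       Y = matrix(y_off + seq_len(h) - 0.5, h, w))
}

# A convex-ish blob: perturbed ellipse with radius r * (1 + sum a_k cos(k t + p_k)).
new_blob <- function(cx, cy, r, n_harmonics = 4) {
  k <- seq_len(n_harmonics) + 1L
  list(cx = cx, cy = cy, r = r,
       a = stats::runif(n_harmonics, 0, 0.12 / seq_along(k)),
       phi = stats::runif(n_harmonics, 0, 2 * pi), k = k)
}

blob_radius <- function(blob, theta) {
  r <- rep(1, length(theta))
  for (i in seq_along(blob$k)) {
    r <- r + blob$a[i] * cos(blob$k[i] * theta + blob$phi[i])
  }
  blob$r * r
}

# Boundary polygon (m x 2 vertex matrix), optionally rescaled about the blob
# center so the shoelace area equals target_area exactly.
blob_polygon <- function(blob, m = 48, target_area = NULL) {
  theta <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  rad <- blob_radius(blob, theta)
  poly <- cbind(blob$cx + rad * cos(theta), blob$cy + rad * sin(theta))
  if (!is.null(target_area)) {
    s <- sqrt(target_area / polygon_area(poly))
    poly <- cbind(blob$cx + s * (poly[, 1] - blob$cx),
                  blob$cy + s * (poly[, 2] - blob$cy))
    attr(poly, "scale") <- s
  }
  poly
}

# Soft-edged inside mask for the blob over coordinate grids, with an optional
# radial scale (to match an area-rescaled polygon).
blob_alpha <- function(blob, X, Y, edge = 2, scale = 1) {
  dx <- X - blob$cx; dy <- Y - blob$cy
  d <- sqrt(dx * dx + dy * dy)
  rad <- scale * blob_radius(blob, atan2(dy, dx))
  clamp01((rad - d) / edge + 0.5)
}

# Smooth interference pattern in [0, 1]; `scale` sets the wavelength band in
# pixels.  Consumes the active RNG stream.
mesh_pattern <- function(X, Y, scale, waves = 3) {
  s <- 0
  for (i in seq_len(waves)) {
    lambda <- stats::runif(1, 0.25, 0.6) * scale
    ang <- stats::runif(1, 0, pi)
    ph <- stats::runif(1, 0, 2 * pi)
    s <- s + sin(2 * pi * (cos(ang) * X + sin(ang) * Y) / lambda + ph)
  }
  (s / waves + 1) / 2
}

# Alpha-blend a solid color onto an image window given an alpha matrix.
blend_color <- function(img, alpha, col) {
  for (ch in 1:3) {
    img[, , ch] <- (1 - alpha) * img[, , ch] + alpha * col[ch]
  }
  img
}

jitter_color <- function(col, jitter) {
  clamp01(col * stats::runif(1, 1 - jitter, 1 + jitter))
}

# Hematoxylin-like background with gentle low-frequency texture.
render_background <- function(h, w, params, x_off = 0, y_off = 0) {
  g <- pixel_grids(h, w, x_off, y_off)
  tex <- 1 + 0.04 * (mesh_pattern(g$X, g$Y, scale = max(h, w), waves = 2) - 0.5)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- params$background_rgb[ch] * tex
  img
}

# Paint one TLS's class-defining marker signal onto an image window.
# `footprint` is the alpha mask of `blob` (radially scaled by `scale`) over
# the window; patterns are scaled to `tile_size` so retained tiles carry the
# class signal.  GC signal combines patterned DAB foci with explicit focus
# blobs (at least one, near the footprint center) so DAB presence is
# guaranteed by construction.
paint_tls_signal <- function(img, X, Y, footprint, code, params, tile_size,
                             blob, scale = 1) {
  # lymphocyte densification (all classes): darker hematoxylin tint
  dense <- footprint * (0.25 + 0.2 * mesh_pattern(X, Y, tile_size * 0.9))
  img <- blend_color(img, dense, c(0.55, 0.55, 0.78))
  if (code >= 1L) {  # CD21+ red FDC meshwork
    red <- jitter_color(params$red_rgb, params$intensity_jitter)
    mesh <- footprint * (0.55 + 0.45 * mesh_pattern(X, Y, tile_size * 0.35))
    img <- blend_color(img, mesh, red)
  }
  if (code == 2L) {  # CD23+ DAB germinal centers
    dab <- jitter_color(params$dab_rgb, params$intensity_jitter)
    p <- mesh_pattern(X, Y, tile_size * 0.45)
    foci <- footprint * ifelse(p > 0.65, 0.8 + 0.2 * p, 0)
    img <- blend_color(img, foci, dab)
    r_eff <- scale * blob$r
    n_foci <- max(1L, stats::rpois(1L, pi * r_eff^2 / tile_size^2))
    for (f in seq_len(n_foci)) {
      u <- if (f == 1L) 0.15 else stats::runif(1, 0, 0.7)  # first focus central
      ang <- stats::runif(1, 0, 2 * pi)
      fb <- new_blob(cx = blob$cx + u * r_eff * cos(ang),
                     cy = blob$cy + u * r_eff * sin(ang),
                     r = tile_size * stats::runif(1, 0.18, 0.24))
      a <- footprint * 0.88 * blob_alpha(fb, X, Y, edge = 3)
      img <- blend_color(img, a, dab)
    }
  }
  img
}

add_artifact <- function(img, X, Y, tile_size) {
  h <- dim(img)[1]; w <- dim(img)[2]
  blob <- new_blob(cx = X[1, 1] + stats::runif(1, 0.2, 0.8) * w,
                   cy = Y[1, 1] + stats::runif(1, 0.2, 0.8) * h,
                   r = tile_size * stats::runif(1, 0.08, 0.15))
  a <- 0.85 * blob_alpha(blob, X, Y, edge = 3)
  blend_color(img, a, c(0.60, 0.60, 0.62))
}

add_pixel_noise <- function(img, noise_sd) {
  if (noise_sd <= 0) return(img)
  clamp01(img + array(stats::rnorm(length(img), 0, noise_sd / 255), dim(img)))
}

# ---- tile generator --------------------------------------------------------

#' Generate one synthetic dual-IHC tile of known maturation class
#'
#' Renders a `size x size` RGB tile carrying the class-defining marker
#' pattern: Aggregate tiles show hematoxylin background and a lymphocyte
#' densification only; Non-GC tiles additionally carry a red CD21 meshwork
#' region; GC tiles carry both the red meshwork and brown DAB CD23 foci
#' nested within it.  Output is deterministic for a fixed seed.
#'
#' @param true_class maturation class (label or code 0/1/2).
#' @param params a [stain_params()] object.
#' @param seed integer seed.
#' @param size tile side in pixels (default 224).
#' @return a `size x size x 3` numeric array in `[0, 1]`.
#' @examples
#' img <- generate_tile("GC", stain_params(), seed = 1, size = 56)
#' stain_fractions(img)
#' @export
generate_tile <- function(true_class, params = stain_params(), seed = 1,
                          size = 224) {
  code <- class_code(true_class)
  stopifnot(length(code) == 1L)
  with_seed(seed, {
    img <- render_background(size, size, params)
    g <- pixel_grids(size, size)
    # TLS-interior footprint: one blob covering roughly a third of the tile
    blob <- new_blob(cx = size * stats::runif(1, 0.42, 0.58),
                     cy = size * stats::runif(1, 0.42, 0.58),
                     r = size * stats::runif(1, 0.30, 0.38))
    footprint <- blob_alpha(blob, g$X, g$Y, edge = 3)
    img <- paint_tls_signal(img, g$X, g$Y, footprint, code, params, size, blob)
    if (stats::runif(1) < params$artifact_rate) {
      img <- add_artifact(img, g$X, g$Y, size)
    }
    add_pixel_noise(img, params$noise_sd)
  })
}

#' Per-pixel stain dominance fractions
#'
#' Classifies every pixel as red-chromogen-dominant, DAB-dominant or
#' background using fixed chromaticity rules (red: `R - G >= 0.35`;
#' DAB: `0.06 < R - G < 0.35` and `G - B >= 0.06`), which are invariant to
#' the generator's multiplicative intensity jitter, and returns the fraction
#' of each.
#'
#' @param img an `h x w x 3` RGB array in `[0, 1]`.
#' @return named numeric vector with elements `red`, `dab`, `background`.
#' @export
stain_fractions <- function(img) {
  rg <- img[, , 1] - img[, , 2]
  gb <- img[, , 2] - img[, , 3]
  red <- rg >= 0.35
  dab <- !red & rg > 0.06 & rg < 0.35 & gb >= 0.06
  c(red = mean(red), dab = mean(dab), background = mean(!red & !dab))
}

#' Rule-based tile classification from stain dominance
#'
#' A fixed color-deconvolution-style classifier: a tile is called GC if its
#' DAB-dominant pixel fraction reaches `dab_threshold`, otherwise Non-GC if
#' its red-dominant fraction reaches `red_threshold`, otherwise Aggregate.
#' Used to verify that the synthetic classes are separable by construction;
#' it is not the learned classifier.
#'
#' @inheritParams stain_fractions
#' @param red_threshold minimum red-dominant pixel fraction for CD21
#'   positivity (default 0.05).
#' @param dab_threshold minimum DAB-dominant pixel fraction for CD23
#'   positivity (default 0.02).
#' @return integer class code (0/1/2).
#' @export
classify_tile_by_stain <- function(img, red_threshold = 0.05,
                                   dab_threshold = 0.02) {
  f <- stain_fractions(img)
  if (f[["dab"]] >= dab_threshold) 2L
  else if (f[["red"]] >= red_threshold) 1L
  else 0L
}

# ---- slide generator -------------------------------------------------------

#' Generate a synthetic annotated slide
#'
#' Places `spec$n_tls` disjoint TLS footprints (perturbed-ellipse blobs) on a
#' canvas, assigns each a maturation class drawn from `spec$class_mix`, and
#' renders the dual-IHC appearance.  Footprint areas are sized so the
#' expected number of retained tiles per TLS matches
#' `spec$mean_tiles_per_tls`.  Placement uses a jittered grid, so polygons
#' are disjoint by construction; if the canvas cannot hold `n_tls` footprints
#' an explicit placement-failure error is raised.
#'
#' @param spec a [synthetic_slide_spec()].
#' @param params a [stain_params()].
#' @param render if `FALSE`, skip pixel rendering and return `image = NULL`
#'   (annotations and truth table only); useful for large statistical checks.
#' @return a list of class `synthetic_slide` with elements `image`
#'   (`h x w x 3` array or `NULL`), `annotations` (list of
#'   [tls_annotation()]), and `truth` (data.frame with columns `tls_id`,
#'   `patient_id`, `slide_id`, `true_class`).
#' @export
generate_slide <- function(spec, params = stain_params(), render = TRUE) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  ts <- spec$tile_size
  n <- spec$n_tls

  setup <- with_seed(spec$seed, {
    classes <- sample(0:2, n, replace = TRUE, prob = spec$class_mix)
    n_target <- 1L + stats::rpois(n, max(spec$mean_tiles_per_tls - 1, 0))
    tls_seeds <- sample.int(.Machine$integer.max - 1L, n)
    perm <- sample.int(n)
    list(classes = classes, n_target = n_target, tls_seeds = tls_seeds,
         perm = perm)
  })
  r0 <- sqrt(setup$n_target * ts^2 / pi)
  margin <- ts
  cell <- ceiling(2 * 1.35 * max(r0)) + 2L

  if (is.null(spec$canvas_size)) {
    side_cells <- ceiling(sqrt(1.3 * n))
    canvas <- rep(2L * margin + side_cells * cell, 2L)
  } else {
    canvas <- as.integer(spec$canvas_size)
  }
  n_cols <- (canvas[1] - 2L * margin) %/% cell
  n_rows <- (canvas[2] - 2L * margin) %/% cell
  if (n_cols < 1L || n_rows < 1L || n_cols * n_rows < n) {
    stopf(paste0("placement failure: canvas %dx%d can hold at most %d disjoint",
                 " TLS footprints of this size, but n_tls = %d"),
          canvas[1], canvas[2], max(0L, n_cols * n_rows), n)
  }

  cells <- with_seed(spec$seed + 1L, sample.int(n_cols * n_rows, n))
  patient_ids <- sprintf("P%03d", 1L + (seq_len(n) - 1L) %% spec$n_patients)
  patient_ids <- patient_ids[order(setup$perm)]

  annotations <- vector("list", n)
  blobs <- vector("list", n)
  scales <- numeric(n)
  for (i in seq_len(n)) {
    ci <- (cells[i] - 1L) %% n_cols
    ri <- (cells[i] - 1L) %/% n_cols
    blobs[[i]] <- with_seed(setup$tls_seeds[i], {
      slack <- max(cell / 2 - 1.35 * r0[i], 0)
      blob <- new_blob(
        cx = margin + ci * cell + cell / 2 + stats::runif(1, -slack, slack),
        cy = margin + ri * cell + cell / 2 + stats::runif(1, -slack, slack),
        r = r0[i])
      blob
    })
    poly <- blob_polygon(blobs[[i]], m = 48,
                         target_area = setup$n_target[i] * ts^2)
    scales[i] <- attr(poly, "scale")
    attr(poly, "scale") <- NULL
    annotations[[i]] <- tls_annotation(
      tls_id = sprintf("TLS_%04d", i), slide_id = spec$slide_id,
      patient_id = patient_ids[i], polygon = poly,
      true_class = setup$classes[i])
  }

  truth <- data.frame(
    tls_id = vapply(annotations, `[[`, "", "tls_id"),
    patient_id = patient_ids,
    slide_id = spec$slide_id,
    true_class = setup$classes,
    stringsAsFactors = FALSE)

  image <- NULL
  if (render) {
    w <- canvas[1]; h <- canvas[2]
    image <- with_seed(spec$seed + 2L,
                       add_pixel_noise(render_background(h, w, params),
                                       params$noise_sd / 2))
    for (i in seq_len(n)) {
      image <- with_seed(setup$tls_seeds[i] + 1L, {
        bb <- polygon_bbox(annotations[[i]]$polygon)
        x0 <- max(floor(bb["xmin"]) - 4L, 0L)
        y0 <- max(floor(bb["ymin"]) - 4L, 0L)
        x1 <- min(ceiling(bb["xmax"]) + 4L, w)
        y1 <- min(ceiling(bb["ymax"]) + 4L, h)
        rows <- (y0 + 1L):y1; cols <- (x0 + 1L):x1
        win <- image[rows, cols, , drop = FALSE]
        g <- pixel_grids(length(rows), length(cols), x_off = x0, y_off = y0)
        fp <- blob_alpha(blobs[[i]], g$X, g$Y, edge = 3, scale = scales[i])
        win <- paint_tls_signal(win, g$X, g$Y, fp, setup$classes[i], params,
                                ts, blobs[[i]], scales[i])
        if (stats::runif(1) < params$artifact_rate) {
          win <- add_artifact(win, g$X, g$Y, ts)
        }
        win <- add_pixel_noise(win, params$noise_sd / 2)
        image[rows, cols, ] <- win
        image
      })
    }
  }

  structure(list(image = image, annotations = annotations, truth = truth,
                 spec = spec),
            class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat("Synthetic dual-IHC slide:", x$spec$slide_id, "\n")
  cat("  TLS:", length(x$annotations),
      "| classes:", paste(sprintf("%s=%d", TLS_CLASS_LABELS,
                                  tabulate(x$truth$true_class + 1L, 3L)),
                          collapse = ", "), "\n")
  if (!is.null(x$image)) {
    cat("  canvas:", dim(x$image)[2], "x", dim(x$image)[1], "px\n")
  } else {
    cat("  canvas: not rendered\n")
  }
  invisible(x)
}

#' Generate a synthetic multi-patient cohort truth table
#'
#' Produces TLS-level ground truth (no images) for a cohort of patients, one
#' slide per patient, with per-patient TLS counts `1 + Poisson(mean - 1)` and
#' classes drawn independently from `class_mix`.  Intended for exercising
#' patient-stratified splitting and cross-validation bookkeeping.
#'
#' @param n_patients number of patients.
#' @param mean_tls_per_patient expected TLS per patient.
#' @param class_mix probabilities of (Aggregate, Non-GC, GC).
#' @param seed integer seed.
#' @return data.frame with columns `tls_id`, `patient_id`, `slide_id`,
#'   `true_class`.
#' @export
generate_cohort <- function(n_patients, mean_tls_per_patient = 10,
                            class_mix = c(0.333, 0.162, 0.505), seed = 1) {
  stopifnot(n_patients >= 1, mean_tls_per_patient >= 1)
  with_seed(seed, {
    n_tls <- 1L + stats::rpois(n_patients, mean_tls_per_patient - 1)
    patient <- rep(sprintf("P%03d", seq_len(n_patients)), n_tls)
    data.frame(
      tls_id = sprintf("TLS_%05d", seq_len(sum(n_tls))),
      patient_id = patient,
      slide_id = sub("^P", "S", patient),
      true_class = sample(0:2, sum(n_tls), replace = TRUE, prob = class_mix),
      stringsAsFactors = FALSE)
  })
}

#' Corrupt ground-truth labels into noisy tile predictions
#'
#' Simulates an imperfect tile classifier: each tile's true label is flipped
#' with probability `epsilon`, the replacement drawn from the corresponding
#' row of `confusion_kernel`; the emitted probability vector places mass
#' `1 - delta` on the (possibly flipped) label, with `delta` drawn uniformly
#' from `delta_range` so confidences vary across tiles.
#'
#' @param truth vector of true maturation classes (labels or codes).
#' @param epsilon per-tile error rate in `[0, 1]`.
#' @param confusion_kernel 3x3 row-stochastic matrix; row i gives the
#'   distribution of the flipped label when the true class is i-1.  Default:
#'   uniform over the other two classes.
#' @param seed integer seed.
#' @param delta_range range of the off-label probability mass.
#' @return data.frame of tile predictions with columns `tile_id`,
#'   `true_class`, `pred_class`, `p_aggregate`, `p_nongc`, `p_gc`,
#'   `confidence`.
#' @examples
#' corrupt_predictions(c(0, 0, 2), epsilon = 0, seed = 1)
#' @export
corrupt_predictions <- function(truth, epsilon,
                                confusion_kernel = NULL, seed = 1,
                                delta_range = c(0.05, 0.25)) {
  codes <- class_code(truth)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 || epsilon > 1) {
    stop("epsilon must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(confusion_kernel)) {
    confusion_kernel <- matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3,
                               byrow = TRUE)
  }
  confusion_kernel <- as.matrix(confusion_kernel)
  if (!all(dim(confusion_kernel) == c(3L, 3L)) ||
      any(confusion_kernel < 0) ||
      any(abs(rowSums(confusion_kernel) - 1) > 1e-8)) {
    stop("confusion_kernel must be a 3x3 row-stochastic matrix", call. = FALSE)
  }
  n <- length(codes)
  with_seed(seed, {
    flip <- stats::runif(n) < epsilon
    pred <- codes
    for (cl in 0:2) {
      idx <- which(flip & codes == cl)
      if (length(idx)) {
        pred[idx] <- sample(0:2, length(idx), replace = TRUE,
                            prob = confusion_kernel[cl + 1L, ])
      }
    }
    delta <- stats::runif(n, delta_range[1], delta_range[2])
    probs <- matrix(rep(delta / 2, 3L), ncol = 3L)
    probs[cbind(seq_len(n), pred + 1L)] <- 1 - delta
    data.frame(tile_id = sprintf("tile_%06d", seq_len(n)),
               true_class = codes, pred_class = pred,
               p_aggregate = probs[, 1], p_nongc = probs[, 2],
               p_gc = probs[, 3], confidence = 1 - delta,
               stringsAsFactors = FALSE)
  })
}
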