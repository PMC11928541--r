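#' Extract non-overlapping tiles from an annotated TLS
#'
#' Lays a `tile_size`-pixel grid anchored at the polygon's bounding-box
#' top-left (floored to the pixel lattice) and retains a grid cell iff the
#' number of pixel centers inside the polygon within that cell is at least
#' `min_overlap_fraction * tile_size^2`.  Overlap is measured by exact
#' pixel-center rasterization, so the rule matches a brute-force
#' point-in-polygon count.  Tiles are returned in row-major grid order with
#' 0-based half-open pixel intervals `[x0, x0 + tile_size)`.
#'
#' @param slide an `h x w x 3` slide image in `[0, 1]`, or `NULL` for
#'   geometry-only extraction (no pixels).
#' @param annotation a [tls_annotation()].
#' @param tile_size tile side in pixels (default 224).
#' @param min_overlap_fraction minimum polygon-covered fraction of a cell for
#'   retention, in `[0, 1]` (default 0.5; 0 retains any intersecting cell).
#' @return a data.frame with columns `tile_id`, `tls_id`, `x0`, `y0`,
#'   `grid_row`, `grid_col`, `overlap_fraction`, plus a `pixels` list-column
#'   when `slide` is given.  A polygon retaining zero tiles yields a
#'   zero-row result with a warning (such TLS are excluded downstream).
#' @export
extract_tiles <- function(slide, annotation, tile_size = 224,
                          min_overlap_fraction = 0.5) {
  stopifnot(inherits(annotation, "tls_annotation"))
  if (min_overlap_fraction < 0 || min_overlap_fraction > 1) {
    stop("min_overlap_fraction must lie in [0, 1]", call. = FALSE)
  }
  ts <- as.integer(tile_size)
  poly <- annotation$polygon
  bb <- polygon_bbox(poly)
  ax <- as.integer(floor(bb["xmin"]))
  ay <- as.integer(floor(bb["ymin"]))
  n_cols <- max(1L, as.integer(ceiling((bb["xmax"] - ax) / ts)))
  n_rows <- max(1L, as.integer(ceiling((bb["ymax"] - ay) / ts)))

  counts <- cell_overlap_counts(poly, ax, ay, ts, n_rows, n_cols)
  # retention: covered pixel centers >= fraction of the cell's pixel count;
  # with fraction 0, any intersecting cell is kept
  need <- if (min_overlap_fraction > 0) min_overlap_fraction * ts^2 else 1
  keep <- which(t(counts) >= need)  # transposed so ordering is row-major

  if (!length(keep)) {
    warning(sprintf("TLS '%s': polygon covers no grid cell at overlap fraction %.2f; no tiles extracted",
                    annotation$tls_id, min_overlap_fraction), call. = FALSE)
    return(empty_tile_frame(has_pixels = !is.null(slide)))
  }

  grid_col <- (keep - 1L) %% n_cols
  grid_row <- (keep - 1L) %/% n_cols
  x0 <- ax + grid_col * ts
  y0 <- ay + grid_row * ts
  overlap <- t(counts)[keep] / ts^2

  if (!is.null(slide)) {
    h <- dim(slide)[1]; w <- dim(slide)[2]
    inside <- x0 >= 0L & y0 >= 0L & (x0 + ts) <= w & (y0 + ts) <= h
    if (!all(inside)) {
      warning(sprintf("TLS '%s': %d tile(s) extend beyond slide bounds and were dropped",
                      annotation$tls_id, sum(!inside)), call. = FALSE)
      grid_col <- grid_col[inside]; grid_row <- grid_row[inside]
      x0 <- x0[inside]; y0 <- y0[inside]; overlap <- overlap[inside]
    }
    if (!length(x0)) return(empty_tile_frame(has_pixels = TRUE))
  }

  out <- data.frame(
    tile_id = sprintf("%s_%s_%d_%d", annotation$slide_id, annotation$tls_id,
                      grid_row, grid_col),
    tls_id = annotation$tls_id,
    x0 = x0, y0 = y0, grid_row = grid_row, grid_col = grid_col,
    overlap_fraction = overlap,
    stringsAsFactors = FALSE)
  if (!is.null(slide)) {
    out$pixels <- lapply(seq_len(nrow(out)), function(i) {
      slide[(y0[i] + 1L):(y0[i] + ts), (x0[i] + 1L):(x0[i] + ts), , drop = FALSE]
    })
  }
  out
}

empty_tile_frame <- function(has_pixels = FALSE) {
  out <- data.frame(tile_id = character(0), tls_id = character(0),
                    x0 = integer(0), y0 = integer(0),
                    grid_row = integer(0), grid_col = integer(0),
                    overlap_fraction = numeric(0), stringsAsFactors = FALSE)
  if (has_pixels) out$pixels <- list()
  out
}

#' Extract tiles for every annotation on a slide
#'
#' Applies [extract_tiles()] to each annotation and binds the results into a
#' tile manifest carrying slide/patient identity and the true class.  TLS
#' retaining zero tiles are listed in the `skipped` attribute.
#'
#' @inheritParams extract_tiles
#' @param annotations list of [tls_annotation()] objects.
#' @return manifest data.frame (see [write_manifest()] for the column
#'   schema), with attribute `skipped` naming excluded TLS.
#' @export
extract_all_tiles <- function(slide, annotations, tile_size = 224,
                              min_overlap_fraction = 0.5) {
  pieces <- list()
  skipped <- character(0)
  for (a in annotations) {
    tl <- extract_tiles(slide, a, tile_size, min_overlap_fraction)
    if (nrow(tl) == 0L) {
      skipped <- c(skipped, a$tls_id)
      next
    }
    tl$slide_id <- a$slide_id
    tl$patient_id <- a$patient_id
    tl$true_class <- a$true_class
    pieces[[length(pieces) + 1L]] <- tl
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else {
    e <- empty_tile_frame(has_pixels = !is.null(slide))
    e$slide_id <- character(0); e$patient_id <- character(0)
    e$true_class <- integer(0)
    e
  }
  attr(out, "skipped") <- skipped
  out
}

#' Render a low-resolution slide overview with the tile grid
#'
#' Downsamples the slide by `scale_factor` (nearest neighbor) and draws each
#' tile's rectangle outline at the scaled coordinates, so the location of
#' every extracted tile is visible at a glance.
#'
#' @param slide an `h x w x 3` image.
#' @param tiles a tile manifest (needs `x0`, `y0` columns) ; may have 0 rows.
#' @param scale_factor in `(0, 1]`.
#' @param tile_size tile side in pixels.
#' @param outline_rgb rectangle color.
#' @return the overview image, dimensions `ceiling(dim(slide) * scale_factor)`.
#' @export
render_overview <- function(slide, tiles, scale_factor = 0.1, tile_size = 224,
                            outline_rgb = c(0.1, 0.9, 0.1)) {
  if (scale_factor <= 0 || scale_factor > 1) {
    stop("scale_factor must lie in (0, 1]", call. = FALSE)
  }
  h <- dim(slide)[1]; w <- dim(slide)[2]
  oh <- as.integer(ceiling(h * scale_factor))
  ow <- as.integer(ceiling(w * scale_factor))
  ri <- pmin(pmax(round((seq_len(oh) - 0.5) / scale_factor + 0.5), 1L), h)
  ci <- pmin(pmax(round((seq_len(ow) - 0.5) / scale_factor + 0.5), 1L), w)
  out <- slide[ri, ci, , drop = FALSE]
  for (i in seq_len(nrow(tiles))) {
    r0 <- max(1L, 1L + as.integer(floor(tiles$y0[i] * scale_factor)))
    c0 <- max(1L, 1L + as.integer(floor(tiles$x0[i] * scale_factor)))
    r1 <- min(oh, as.integer(ceiling((tiles$y0[i] + tile_size) * scale_factor)))
    c1 <- min(ow, as.integer(ceiling((tiles$x0[i] + tile_size) * scale_factor)))
    for (ch in 1:3) {
      out[c(r0, r1), c0:c1, ch] <- outline_rgb[ch]
      out[r0:r1, c(c0, c1), ch] <- outline_rgb[ch]
    }
  }
  out
}

MANIFEST_COLUMNS <- c("tile_id", "tile_path", "slide_id", "patient_id",
                      "tls_id", "x0", "y0", "grid_row", "grid_col",
                      "true_class")

#' Write and read tile manifests
#'
#' The manifest CSV has one row per tile with columns `tile_id`, `tile_path`,
#' `slide_id`, `patient_id`, `tls_id`, `x0`, `y0`, `grid_row`, `grid_col`,
#' `true_class`, ordered by `tls_id` then grid position.  A commented header
#' documents the coordinate convention (0-based, half-open `[x0, x0 + size)`,
#' y-down).  Every tile's parent TLS must be present among `annotations`.
#'
#' @param tiles tile manifest data.frame from [extract_all_tiles()] (or with
#'   the same columns).
#' @param annotations list of [tls_annotation()] objects (referential check);
#'   also supplies `slide_id` / `patient_id` / `true_class` if absent.
#' @param path output CSV path.
#' @param tile_size tile side, recorded in the header comment.
#' @return `write_manifest()`: the manifest data.frame as written,
#'   invisibly; `read_manifest()`: the manifest data.frame.
#' @export
write_manifest <- function(tiles, annotations, path, tile_size = 224) {
  ann_ids <- vapply(annotations, `[[`, "", "tls_id")
  orphans <- setdiff(unique(tiles$tls_id), ann_ids)
  if (length(orphans)) {
    stopf("referential-integrity error: tile(s) reference unknown TLS: %s",
          paste(orphans, collapse = ", "))
  }
  idx <- match(tiles$tls_id, ann_ids)
  m <- data.frame(
    tile_id = tiles$tile_id,
    tile_path = if ("tile_path" %in% names(tiles)) tiles$tile_path else "",
    slide_id = vapply(annotations, `[[`, "", "slide_id")[idx],
    patient_id = vapply(annotations, `[[`, "", "patient_id")[idx],
    tls_id = tiles$tls_id,
    x0 = tiles$x0, y0 = tiles$y0,
    grid_row = tiles$grid_row, grid_col = tiles$grid_col,
    true_class = vapply(annotations, function(a) a$true_class, 0L)[idx],
    stringsAsFactors = FALSE)
  m <- m[order(m$tls_id, m$grid_row, m$grid_col), , drop = FALSE]
  rownames(m) <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# tile manifest: %d x %d px tiles; coordinates 0-based, y-down;",
            tile_size, tile_size),
    "# tiles cover the half-open interval [x0, x0+size) x [y0, y0+size);",
    "# true_class encoding: 0=Aggregate, 1=Non-GC, 2=GC"), con)
  utils::write.csv(m, con, row.names = FALSE)
  invisible(m)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = c(tile_id = "character",
                                      tile_path = "character",
                                      slide_id = "character",
                                      patient_id = "character",
                                      tls_id = "character"))
  missing <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(missing)) {
    stopf("manifest '%s' is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  if (!nrow(m)) m$tile_path <- character(0)
  m
}

#' Write per-tile PNG images
#'
#' Writes each tile's pixels as `{slide_id}_{tls_id}_{grid_row}_{grid_col}.png`
#' under `dir` and fills the manifest's `tile_path` column.
#'
#' @param tiles tile manifest with a `pixels` list-column and identity columns.
#' @param dir output directory (created if needed).
#' @return the manifest with `tile_path` set, pixels column dropped.
#' @export
write_tile_images <- function(tiles, dir) {
  stopifnot("pixels" %in% names(tiles))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_%s_%d_%d.png", tiles$slide_id,
                                  tiles$tls_id, tiles$grid_row,
                                  tiles$grid_col))
  for (i in seq_len(nrow(tiles))) write_image(tiles$pixels[[i]], paths[i])
  tiles$tile_path <- paths
  tiles$pixels <- NULL
  tiles
}
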