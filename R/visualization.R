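#' Class color map for prediction rendering
#'
#' The rendered convention colors predicted classes blue (class 1 display
#' numbering, Aggregate), green (class 2, Non-GC) and red (class 3, GC);
#' internally classes stay 0/1/2.
#'
#' @param aggregate_rgb,nongc_rgb,gc_rgb tint colors.
#' @param tint_alpha blend fraction in `(0, 1]`; the default 0.4 keeps tissue
#'   texture visible under the class color.
#' @return object of class `class_colormap`.
#' @export
class_colormap <- function(aggregate_rgb = c(0.15, 0.25, 0.95),
                           nongc_rgb = c(0.10, 0.75, 0.20),
                           gc_rgb = c(0.90, 0.10, 0.10),
                           tint_alpha = 0.4) {
  cols <- list(aggregate_rgb, nongc_rgb, gc_rgb)
  if (!all(vapply(cols, is_rgb_color, TRUE))) {
    stop("tint colors must be RGB triples in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(vapply(cols, paste, "", collapse = ","))) {
    stop("the three class colors must be distinct", call. = FALSE)
  }
  if (tint_alpha <= 0 || tint_alpha > 1) {
    stop("tint_alpha must lie in (0, 1]", call. = FALSE)
  }
  structure(list(colors = cols, tint_alpha = tint_alpha),
            class = "class_colormap")
}

#' Tint a tile with its predicted class color
#'
#' Alpha-blends the tile with the solid class color:
#' `out = (1 - alpha) * tile + alpha * color`.
#'
#' @param tile `h x w x 3` RGB array.
#' @param pred_class predicted maturation class (label or code).
#' @param colormap a [class_colormap()].
#' @return tinted image, same dimensions.
#' @export
colorize_tile <- function(tile, pred_class, colormap = class_colormap()) {
  code <- class_code(pred_class)
  stopifnot(length(code) == 1L)
  col <- colormap$colors[[code + 1L]]
  a <- colormap$tint_alpha
  out <- tile
  for (ch in 1:3) out[, , ch] <- (1 - a) * tile[, , ch] + a * col[ch]
  out
}

#' Reassemble a TLS mosaic from its tiles
#'
#' Places each tile at its grid position; the mosaic spans the occupied grid
#' range, `(max_row - min_row + 1) x (max_col - min_col + 1)` cells, and grid
#' cells without a tile are filled with a neutral background (white by
#' default) to distinguish absent tissue from any class color.
#'
#' @param tiles data.frame with `grid_row`, `grid_col` (one TLS).
#' @param images list of `tile_size`-square RGB arrays aligned with
#'   `tiles` rows.
#' @param fill neutral RGB fill for absent cells.
#' @return mosaic RGB array.
#' @export
reassemble_tls <- function(tiles, images, fill = c(1, 1, 1)) {
  stopifnot(nrow(tiles) >= 1L, length(images) == nrow(tiles))
  if (anyDuplicated(tiles[, c("grid_row", "grid_col")])) {
    stop("duplicate grid cell among tiles of one TLS", call. = FALSE)
  }
  ts <- dim(images[[1L]])[1]
  r0 <- min(tiles$grid_row); c0 <- min(tiles$grid_col)
  nr <- max(tiles$grid_row) - r0 + 1L
  nc <- max(tiles$grid_col) - c0 + 1L
  mosaic <- array(rep(fill, each = nr * ts * nc * ts), c(nr * ts, nc * ts, 3L))
  for (i in seq_len(nrow(tiles))) {
    img <- images[[i]]
    if (!all(dim(img) == c(ts, ts, 3L))) {
      stopf("tile %d has dimensions %s, expected %dx%dx3", i,
            paste(dim(img), collapse = "x"), ts, ts)
    }
    rr <- (tiles$grid_row[i] - r0) * ts
    cc <- (tiles$grid_col[i] - c0) * ts
    mosaic[(rr + 1L):(rr + ts), (cc + 1L):(cc + ts), ] <- img
  }
  mosaic
}

#' Write prediction CSVs and class-tinted TLS mosaics
#'
#' Produces the pipeline's visual outputs: a tile-level CSV
#' (`tile_id, tls_id, p_aggregate, p_nongc, p_gc, pred_class, confidence`),
#' a TLS-level CSV (`tls_id, method, pred_class, support, tie_broken`), and
#' one mosaic PNG per TLS per requested method
#' (named `{tls_id}_{method}.png`), each tile tinted with its predicted
#' class color.
#'
#' @param tile_preds tile predictions from [predict_tiles()] with `tls_id`.
#' @param tls_preds TLS predictions from [aggregate_all()].
#' @param manifest tile manifest supplying grid coordinates and pixels
#'   (`pixels` list-column or `tile_path`).
#' @param out_dir output directory (created if needed).
#' @param colormap a [class_colormap()].
#' @return invisible list of written paths (`tile_csv`, `tls_csv`,
#'   `mosaics`).
#' @export
write_prediction_outputs <- function(tile_preds, tls_preds, manifest, out_dir,
                                     colormap = class_colormap()) {
  if (!all(tile_preds$tls_id %in% tls_preds$tls_id) ||
      !all(tls_preds$tls_id %in% tile_preds$tls_id)) {
    stop("inconsistent tls_id sets between tile and TLS predictions",
         call. = FALSE)
  }
  if (!all(tile_preds$tile_id %in% manifest$tile_id)) {
    stop("tile predictions reference tiles absent from the manifest",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tile_csv <- file.path(out_dir, "tile_predictions.csv")
  cols <- c("tile_id", "tls_id", "p_aggregate", "p_nongc", "p_gc",
            "pred_class", "confidence")
  utils::write.csv(tile_preds[, cols], tile_csv, row.names = FALSE)
  tls_csv <- file.path(out_dir, "tls_predictions.csv")
  utils::write.csv(tls_preds, tls_csv, row.names = FALSE)

  mi <- match(tile_preds$tile_id, manifest$tile_id)
  mosaics <- character(0)
  for (id in unique(tls_preds$tls_id)) {
    sel <- which(tile_preds$tls_id == id)
    rows <- manifest[mi[sel], , drop = FALSE]
    imgs <- lapply(seq_along(sel), function(j) {
      img <- if (!is.null(rows$pixels)) rows$pixels[[j]]
             else read_image(rows$tile_path[j])
      colorize_tile(img, tile_preds$pred_class[sel[j]], colormap)
    })
    mosaic <- reassemble_tls(rows, imgs)
    for (m in unique(tls_preds$method[tls_preds$tls_id == id])) {
      p <- file.path(out_dir, sprintf("%s_%s.png", id, m))
      write_image(mosaic, p)
      mosaics <- c(mosaics, p)
    }
  }
  invisible(list(tile_csv = tile_csv, tls_csv = tls_csv, mosaics = mosaics))
}
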