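#' @keywords internal
"_PACKAGE"

# Internal class encoding: 0 = Aggregate (CD21-/CD23-), 1 = Non-GC (CD21+/CD23-),
# 2 = GC (CD21+/CD23+).  Display numbering in figures/CSVs is 1/2/3.
TLS_CLASS_LABELS <- c("Aggregate", "Non-GC", "GC")
TLS_CLASS_CODES <- 0:2

#' Maturation class labels and codes
#'
#' The three tertiary lymphoid structure maturation stages are encoded as
#' integers 0 (Aggregate, CD21-/CD23-), 1 (Non-GC, CD21+/CD23-) and
#' 2 (GC, CD21+/CD23+).  `class_code()` maps labels or codes to the internal
#' integer encoding; `class_label()` does the reverse; `display_class()`
#' returns the 1-based numbering used in rendered outputs.
#'
#' @param x class labels (`"Aggregate"`, `"Non-GC"`, `"GC"`) or integer codes.
#' @return `class_code()`: integer vector in `0:2`; `class_label()`:
#'   character vector; `display_class()`: integer vector in `1:3`.
#' @examples
#' class_code(c("GC", "Aggregate"))
#' class_label(0:2)
#' @export
class_code <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    idx <- match(x, TLS_CLASS_LABELS)
    if (anyNA(idx)) {
      bad <- unique(x[is.na(idx)])
      stop("unknown maturation class label(s): ", paste(bad, collapse = ", "),
           "; expected one of ", paste(TLS_CLASS_LABELS, collapse = ", "),
           call. = FALSE)
    }
    return(idx - 1L)
  }
  x <- as.integer(x)
  if (anyNA(x) || any(x < 0L | x > 2L)) {
    stop("maturation class codes must be integers in 0:2 ",
         "(0=Aggregate, 1=Non-GC, 2=GC)", call. = FALSE)
  }
  x
}

#' @rdname class_code
#' @param code integer class codes in `0:2`.
#' @export
class_label <- function(code) TLS_CLASS_LABELS[class_code(code) + 1L]

#' @rdname class_code
#' @export
display_class <- function(code) class_code(code) + 1L

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library use does not disturb user
# simulations.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Hierarchical seed derivation: n child seeds drawn reproducibly from a
# parent seed, so every sub-object (TLS, tile, epoch) is independently
# reproducible.  Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_rgb_color <- function(x) {
  is.numeric(x) && length(x) == 3L && !anyNA(x) && all(x >= 0) && all(x <= 1)
}

#' Read and write RGB images
#'
#' Images are represented throughout the package as numeric arrays of
#' dimension `height x width x 3` with values in `[0, 1]`, y-down, 0-based
#' pixel coordinates.  PNG is read natively; TIFF is supported when the
#' `tiff` package is available (pyramidal TIFFs are read at level 0).
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @param img numeric `h x w x 3` array in `[0, 1]`.
#' @return `read_image()`: an `h x w x 3` array; `write_image()`: `path`,
#'   invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stopf("reading '%s' requires the 'tiff' package", path)
    }
    out <- tiff::readTIFF(path)
    if (is.list(out)) out <- out[[1L]]  # level 0 of a multi-page/pyramidal file
    out
  } else {
    stopf("unsupported image format '%s' (use PNG or TIFF)", ext)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  ext <- tolower(tools::file_ext(path))
  img <- clamp01(img)
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stopf("writing '%s' requires the 'tiff' package", path)
    }
    tiff::writeTIFF(img, path)
  } else {
    stopf("unsupported image format '%s' (use PNG or TIFF)", ext)
  }
  invisible(path)
}
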