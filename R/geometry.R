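# Plain-R polygon geometry for tile extraction.  Coordinates are pixel
# units, 0-based, y-down; the pixel with integer coordinates (i, j) covers
# [i, i+1) x [j, j+1) and has center (i + 0.5, j + 0.5).

# Shoelace area of a simple polygon given as an n x 2 matrix of vertices.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), ymin = min(poly[, 2]),
    xmax = max(poly[, 1]), ymax = max(poly[, 2]))
}

# Even-odd ray-casting point-in-polygon, vectorized over query points.
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py))
    if (any(crosses)) {
      xint <- x[i] + (py[crosses] - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

# Exact pixel-center rasterization of a polygon onto a tile grid.
#
# The grid is anchored at (ax, ay) with square cells of side `ts`; the
# returned integer matrix has one entry per grid cell (row-major layout as
# [row, col]) counting the pixel centers inside the polygon that fall in
# that cell.  Implemented as a row scanline: for each pixel row, edge
# crossings at the row's center y give the inside x-intervals, which are
# converted to integer pixel runs and binned into grid columns.  This is the
# package's definition of cell/polygon overlap, matching what a brute-force
# point-in-polygon test over every pixel center computes.
cell_overlap_counts <- function(poly, ax, ay, ts, n_rows, n_cols) {
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  counts <- matrix(0L, nrow = n_rows, ncol = n_cols)
  x_max_px <- ax + n_cols * ts - 1L  # last pixel column in the grid

  for (r in seq_len(n_rows)) {
    row_counts <- integer(n_cols)
    for (pr in 0:(ts - 1L)) {
      yc <- ay + (r - 1L) * ts + pr + 0.5
      cross <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
      if (!any(cross)) next
      xs <- sort(x1[cross] + (yc - y1[cross]) * (x2[cross] - x1[cross]) /
                   (y2[cross] - y1[cross]))
      nx <- length(xs)
      if (nx %% 2L != 0L) next  # degenerate (vertex exactly on scanline)
      for (k in seq.int(1L, nx - 1L, by = 2L)) {
        # pixel centers i + 0.5 strictly inside (xs[k], xs[k+1]]
        i0 <- max(floor(xs[k] - 0.5) + 1L, ax)
        i1 <- min(floor(xs[k + 1L] - 0.5), x_max_px)
        if (i1 < i0) next
        c0 <- (i0 - ax) %/% ts
        c1 <- (i1 - ax) %/% ts
        for (cc in c0:c1) {
          lo <- max(i0, ax + cc * ts)
          hi <- min(i1, ax + (cc + 1L) * ts - 1L)
          row_counts[cc + 1L] <- row_counts[cc + 1L] + (hi - lo + 1L)
        }
      }
    }
    counts[r, ] <- row_counts
  }
  counts
}
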