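#' Bilinear resampling of a continuous raster
#'
#' Evaluates the source grid at every target cell center by bilinear
#' interpolation between the four nearest source cell centers. Target centers
#' outside the source extent are nodata; centers inside the extent but
#' beyond the outermost ring of source centers use the clamped (edge) value.
#' Any `NA` among the contributing source cells propagates. Intended for
#' continuous layers only (climate, percent cover); categorical layers must
#' not be passed through it.
#'
#' @param src A [grid_layer()] with continuous values.
#' @param target A [grid_spec()] overlapping the source extent.
#' @return A [grid_layer()] on `target`.
#' @export
resample_bilinear <- function(src, target) {
  stopifnot(inherits(src, "grid_layer"), inherits(target, "grid_spec"))
  ss <- src$spec
  ctr <- cell_center(target,
                     rows = rep(seq_len(target$n_rows), target$n_cols),
                     cols = rep(seq_len(target$n_cols), each = target$n_rows))
  # fractional (0-based) position on the source center lattice
  gx <- (ctr[, "x"] - ss$origin_x) / ss$cell_size - 0.5
  gy <- (ss$origin_y - ctr[, "y"]) / ss$cell_size - 0.5
  inside <- ctr[, "x"] >= ss$origin_x &
    ctr[, "x"] < ss$origin_x + ss$n_cols * ss$cell_size &
    ctr[, "y"] <= ss$origin_y &
    ctr[, "y"] > ss$origin_y - ss$n_rows * ss$cell_size
  gx <- pmin(pmax(gx, 0), ss$n_cols - 1)
  gy <- pmin(pmax(gy, 0), ss$n_rows - 1)
  c0 <- pmin(floor(gx), ss$n_cols - 2); c0 <- pmax(c0, 0)
  r0 <- pmin(floor(gy), ss$n_rows - 2); r0 <- pmax(r0, 0)
  if (ss$n_cols == 1) c0 <- rep(0, length(gx))
  if (ss$n_rows == 1) r0 <- rep(0, length(gy))
  fx <- gx - c0
  fy <- gy - r0
  v <- src$values
  at <- function(r, c) v[cbind(pmin(r, ss$n_rows - 1) + 1, pmin(c, ss$n_cols - 1) + 1)]
  v00 <- at(r0, c0); v01 <- at(r0, c0 + 1)
  v10 <- at(r0 + 1, c0); v11 <- at(r0 + 1, c0 + 1)
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out[!inside] <- NA_real_
  grid_layer(matrix(out, nrow = target$n_rows, ncol = target$n_cols),
             target)
}

# Cells traversed by one segment, half-open pixel convention: split the
# segment at every grid-line crossing and assign each piece's midpoint to its
# pixel. Zero-length segments mark the single pixel containing the point.
segment_cells <- function(x1, y1, x2, y2, spec) {
  if (x1 == x2 && y1 == y2) {
    rc <- xy_to_rowcol(spec, x1, y1)
    return(rc[!is.na(rc[, 1]), , drop = FALSE])
  }
  ts <- c(0, 1)
  if (x1 != x2) {
    k <- sort(c(floor((x1 - spec$origin_x) / spec$cell_size),
                floor((x2 - spec$origin_x) / spec$cell_size)))
    kk <- seq(k[1] + 1, k[2], length.out = max(0, k[2] - k[1]))
    if (length(kk)) ts <- c(ts, ((spec$origin_x + kk * spec$cell_size) - x1) / (x2 - x1))
  }
  if (y1 != y2) {
    k <- sort(c(floor((spec$origin_y - y1) / spec$cell_size),
                floor((spec$origin_y - y2) / spec$cell_size)))
    kk <- seq(k[1] + 1, k[2], length.out = max(0, k[2] - k[1]))
    if (length(kk)) ts <- c(ts, ((spec$origin_y - kk * spec$cell_size) - y1) / (y1 - y2))
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  mx <- x1 + mid * (x2 - x1)
  my <- y1 + mid * (y2 - y1)
  rc <- xy_to_rowcol(spec, mx, my)
  rc[!is.na(rc[, 1]), , drop = FALSE]
}

#' Rasterize polylines onto a binary grid
#'
#' A cell becomes 1 if any segment of any polyline passes through it
#' ("all-touched" with the grid's half-open pixel convention); all other
#' cells are 0. An empty polyline list yields an all-zero grid.
#'
#' @param lines List of two-column (x, y) coordinate matrices, each an
#'   ordered polyline.
#' @param spec Target [grid_spec()].
#' @return Binary [grid_layer()].
#' @export
rasterize_lines <- function(lines, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  m <- matrix(0, spec$n_rows, spec$n_cols)
  for (ln in lines) {
    ln <- as.matrix(ln)
    if (nrow(ln) == 1) {
      rc <- segment_cells(ln[1, 1], ln[1, 2], ln[1, 1], ln[1, 2], spec)
      if (nrow(rc)) m[rc] <- 1
      next
    }
    for (i in seq_len(nrow(ln) - 1)) {
      rc <- segment_cells(ln[i, 1], ln[i, 2], ln[i + 1, 1], ln[i + 1, 2], spec)
      if (nrow(rc)) m[rc] <- 1
    }
  }
  grid_layer(m, spec)
}

#' Rasterize polygons onto an integer-label grid
#'
#' Each cell takes the id of the polygon containing its center; 0 is
#' background. Where polygons overlap, the lowest id wins and a warning is
#' emitted. Point-in-polygon testing uses `mgcv::in.out`.
#'
#' @param polygons Named or unnamed list; each element is either a
#'   two-column vertex matrix (one ring) or a list whose first element is the
#'   outer ring.
#' @param ids Positive integer id per polygon.
#' @param spec Target [grid_spec()].
#' @return Integer-labelled [grid_layer()].
#' @export
rasterize_polygons <- function(polygons, ids, spec) {
  stopifnot(length(polygons) == length(ids), all(ids >= 1))
  m <- matrix(0, spec$n_rows, spec$n_cols)
  ctr <- cell_center(spec,
                     rows = rep(seq_len(spec$n_rows), spec$n_cols),
                     cols = rep(seq_len(spec$n_cols), each = spec$n_rows))
  overlap <- FALSE
  for (k in order(ids, decreasing = TRUE)) {
    ring <- polygons[[k]]
    if (is.list(ring) && !is.matrix(ring)) ring <- ring[[1]]
    ring <- as.matrix(ring)
    # close the ring if open
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    inside <- mgcv::in.out(ring, ctr)
    if (any(inside & as.vector(m) != 0)) overlap <- TRUE
    m[matrix(inside, spec$n_rows, spec$n_cols)] <- ids[k]
  }
  if (overlap)
    warning("overlapping polygons: lowest id wins at contested cells")
  grid_layer(m, spec)
}
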