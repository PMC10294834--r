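# Pad a matrix by replicating its border `k` cells outward.
pad_replicate <- function(m, k = 1) {
  r <- nrow(m); c <- ncol(m)
  ri <- c(rep(1, k), seq_len(r), rep(r, k))
  ci <- c(rep(1, k), seq_len(c), rep(c, k))
  m[ri, ci, drop = FALSE]
}

#' Slope from a DEM (Horn operator)
#'
#' Per-cell slope in degrees from the standard 3x3 Horn finite-difference
#' operator: `atan(sqrt((dz/dx)^2 + (dz/dy)^2))`. The DEM's cell size must be
#' in the same linear units as its elevations. Borders are handled by
#' replication; `NA` cells propagate (a cell is `NA` if any of its 3x3
#' neighbors is).
#'
#' @param dem A [grid_layer()] of elevations.
#' @return A [grid_layer()] of slopes in degrees.
#' @export
terrain_slope <- function(dem) {
  stopifnot(inherits(dem, "grid_layer"))
  s <- dem$spec
  if (s$n_rows < 2 || s$n_cols < 2)
    stop("slope needs a grid of at least 2 x 2 cells")
  p <- pad_replicate(dem$values, 1)
  r <- s$n_rows; c <- s$n_cols
  sub <- function(dr, dc) p[seq_len(r) + 1 + dr, seq_len(c) + 1 + dc, drop = FALSE]
  a <- sub(-1, -1); b <- sub(-1, 0); cc <- sub(-1, 1)
  d <- sub(0, -1);                   f <- sub(0, 1)
  g <- sub(1, -1);  h <- sub(1, 0);  i <- sub(1, 1)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * s$cell_size)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * s$cell_size)
  out <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  out[is.na(dem$values)] <- NA_real_   # the kernel skips the center cell
  grid_layer(out, s)
}

# Summed-area window sums with truncation at the borders: for each cell, the
# sum (and count) of non-NA values in the (2r+1)^2 window clipped to the grid.
window_stats <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  vals <- m; vals[is.na(vals)] <- 0
  cnts <- matrix(as.numeric(!is.na(m)), nr, nc)
  sat <- function(x) {
    x <- apply(x, 2, cumsum)
    t(apply(x, 1, cumsum))
  }
  Sv <- rbind(0, cbind(0, sat(vals)))
  Sc <- rbind(0, cbind(0, sat(cnts)))
  r1 <- pmax(seq_len(nr) - radius, 1); r2 <- pmin(seq_len(nr) + radius, nr)
  c1 <- pmax(seq_len(nc) - radius, 1); c2 <- pmin(seq_len(nc) + radius, nc)
  win <- function(S) {
    S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
      S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  }
  list(sum = win(Sv), count = win(Sc))
}

#' Topographic position index
#'
#' TPI of a cell is its elevation minus the mean elevation of its square
#' `(2*radius+1)^2` neighborhood, center excluded. Negative values mark
#' valley positions, positive values ridges. At the borders only the
#' available neighbors enter the mean; `NA` cells propagate and are excluded
#' from their neighbors' means.
#'
#' @param dem A [grid_layer()] of elevations.
#' @param radius Neighborhood half-width in cells (>= 1). The default 1
#'   (3x3 window) matches the analysis resolution; larger radii give
#'   broader-scale landform context.
#' @return A [grid_layer()] of TPI values (same units as the DEM).
#' @export
terrain_tpi <- function(dem, radius = 1) {
  stopifnot(inherits(dem, "grid_layer"))
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1")
  s <- dem$spec
  if (2 * radius + 1 > min(s$n_rows, s$n_cols))
    stop("radius ", radius, " is too large for a ",
         s$n_rows, " x ", s$n_cols, " grid")
  w <- window_stats(dem$values, radius)
  v <- dem$values
  nb_sum <- w$sum - ifelse(is.na(v), 0, v)
  nb_cnt <- w$count - as.numeric(!is.na(v))
  tpi <- v - nb_sum / nb_cnt
  tpi[nb_cnt == 0] <- NA_real_
  grid_layer(tpi, s)
}
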