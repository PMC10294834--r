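#' Grid geometry specification
#'
#' Defines the geometry of a single-band raster: dimensions, top-left map
#' origin, square cell size, an opaque CRS tag, and the nodata sentinel used
#' when the grid is written to disk (internally, masked cells are `NA`).
#' Pixel `(r, c)` (1-based) covers the half-open square
#' `[origin_x + (c-1)*cell, origin_x + c*cell)` in x and
#' `(origin_y - r*cell, origin_y - (r-1)*cell]` in y, so row index increases
#' southward and a point maps to a pixel by `floor((x - origin_x)/cell)`.
#'
#' @param n_rows,n_cols Positive integers.
#' @param cell_size Cell edge length in map units (square pixels), > 0.
#' @param origin_x,origin_y Map coordinates of the grid's top-left corner.
#'   `origin_y` defaults to `n_rows * cell_size` so the lower-left corner
#'   sits at (0, 0).
#' @param crs_tag Opaque CRS string carried through I/O; never interpreted.
#' @param nodata Sentinel written for masked cells.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 30,
                      origin_x = 0, origin_y = n_rows * cell_size,
                      crs_tag = "local", nodata = -9999) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, cell_size > 0, is.finite(origin_x),
            is.finite(origin_y), is.finite(nodata))
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_tag = as.character(crs_tag), nodata = as.numeric(nodata)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g map units, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_tag))
  invisible(x)
}

spec_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

#' Single-band raster grid
#'
#' Couples a numeric matrix (row 1 = northernmost row) with a [grid_spec()].
#' Masked cells are stored as `NA`; the spec's `nodata` sentinel is only used
#' on disk.
#'
#' @param values Numeric matrix, `n_rows x n_cols`.
#' @param spec A [grid_spec()] matching `dim(values)`.
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(values, spec) {
  stopifnot(inherits(spec, "grid_spec"), is.matrix(values))
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop("values matrix (", nrow(values), "x", ncol(values),
         ") does not match spec (", spec$n_rows, "x", spec$n_cols, ")")
  storage.mode(values) <- "double"
  if (any(is.infinite(values)))
    stop("grid values must be finite or NA")
  structure(list(spec = spec, values = values), class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<grid_layer> %d x %d @ %g; %d valid cells; range [%s, %s]\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$cell_size,
              length(v),
              if (length(v)) format(min(v)) else "NA",
              if (length(v)) format(max(v)) else "NA"))
  invisible(x)
}

#' Map coordinates of cell centers
#'
#' @param spec A [grid_spec()].
#' @param rows,cols 1-based row/column indices (recycled together).
#' @return Two-column matrix of (x, y) center coordinates.
#' @export
cell_center <- function(spec, rows, cols) {
  cbind(x = spec$origin_x + (cols - 0.5) * spec$cell_size,
        y = spec$origin_y - (rows - 0.5) * spec$cell_size)
}

#' Locate points on the grid
#'
#' Maps map coordinates to 1-based (row, col) indices using the half-open
#' pixel convention (`floor`); points outside the extent get `NA`.
#'
#' @param spec A [grid_spec()].
#' @param x,y Numeric coordinate vectors.
#' @return Two-column integer matrix (row, col).
#' @export
xy_to_rowcol <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1
  row <- floor((spec$origin_y - y) / spec$cell_size) + 1
  bad <- row < 1 | row > spec$n_rows | col < 1 | col > spec$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Area represented by a cell count
#'
#' Raster-native area: count times the squared cell size. `divisor` converts
#' map units; the default turns meters into square kilometers.
#'
#' @param n_cells Number of cells.
#' @param spec A [grid_spec()].
#' @param divisor Unit conversion divisor applied to the map-unit area.
#' @export
cell_area <- function(n_cells, spec, divisor = 1e6) {
  n_cells * spec$cell_size^2 / divisor
}

#' Stack of co-registered predictor grids
#'
#' @param layers Named list of [grid_layer()] objects sharing one geometry.
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  nms <- names(layers)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("layers must be uniquely named")
  ref <- layers[[1]]$spec
  for (nm in nms) {
    if (!inherits(layers[[nm]], "grid_layer"))
      stop("layer '", nm, "' is not a grid_layer")
    if (!spec_equal(layers[[nm]]$spec, ref))
      stop("layer '", nm, "' does not share the stack geometry")
  }
  structure(list(names = nms, layers = layers, spec = ref),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %d layers (%s) on %d x %d grid\n",
              length(x$names), paste(x$names, collapse = ", "),
              x$spec$n_rows, x$spec$n_cols))
  invisible(x)
}

#' Extract covariate values at point locations
#'
#' @param stack A [predictor_stack()].
#' @param x,y Point coordinates.
#' @return Data frame with one column per stack layer; rows for points
#'   outside the extent (or on nodata cells) contain `NA`.
#' @export
stack_extract <- function(stack, x, y) {
  rc <- xy_to_rowcol(stack$spec, x, y)
  idx <- cbind(rc[, "row"], rc[, "col"])
  out <- lapply(stack$layers, function(g) {
    v <- rep(NA_real_, nrow(idx))
    ok <- !is.na(idx[, 1])
    v[ok] <- g$values[idx[ok, , drop = FALSE]]
    v
  })
  as.data.frame(out)
}

#' Point set (presences or pseudo-absences)
#'
#' Light wrapper: a data frame with columns `species`, `x`, `y`, `label`
#' (1 = presence, 0 = pseudo-absence).
#'
#' @param species Character scalar or vector.
#' @param x,y Coordinates.
#' @param label 0/1 vector.
#' @export
point_set <- function(species, x, y, label) {
  stopifnot(all(label %in% c(0, 1)))
  data.frame(species = species, x = as.numeric(x), y = as.numeric(y),
             label = as.integer(label))
}

# Run code with a temporary RNG state seeded at `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
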