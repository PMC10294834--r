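#' Read a raster from an ESRI ASCII grid file
#'
#' The on-disk format is the plain-text ESRI ASCII grid (.asc): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, northernmost row first. A
#' sidecar `<path>.prj`, if present, supplies the CRS tag. Values are written
#' with 17 significant digits so a write/read round trip is bit-exact.
#'
#' @param path Path to a `.asc` file.
#' @return A [grid_layer()]; nodata cells become `NA`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header line: ", ln)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(req %in% names(hdr)))
    stop("ASCII grid header missing fields: ",
         paste(setdiff(req, names(hdr)), collapse = ", "))
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE,
               na.strings = character())
  if (length(vals) != n_rows * n_cols)
    stop("expected ", n_rows * n_cols, " values, found ", length(vals),
         " (multi-band or truncated input?)")
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  prj <- paste0(path, ".prj")
  crs <- if (file.exists(prj)) readLines(prj, n = 1L) else "local"
  spec <- grid_spec(n_rows, n_cols, cell_size = hdr$cellsize,
                    origin_x = hdr$xllcorner,
                    origin_y = hdr$yllcorner + n_rows * hdr$cellsize,
                    crs_tag = crs, nodata = hdr$nodata_value)
  grid_layer(m, spec)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param grid A [grid_layer()].
#' @param path Output path; a `<path>.prj` sidecar holds the CRS tag.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "grid_layer"))
  s <- grid$spec
  v <- grid$values
  if (any(v == s$nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel ", s$nodata,
         " as a data value; choose a different sentinel")
  v[is.na(v)] <- s$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", s$n_cols),
    paste("nrows", s$n_rows),
    paste("xllcorner", sprintf("%.17g", s$origin_x)),
    paste("yllcorner", sprintf("%.17g", s$origin_y - s$n_rows * s$cell_size)),
    paste("cellsize", sprintf("%.17g", s$cell_size)),
    paste("NODATA_value", sprintf("%.17g", s$nodata))
  ), con)
  for (r in seq_len(s$n_rows))
    writeLines(paste(sprintf("%.17g", v[r, ]), collapse = " "), con)
  writeLines(s$crs_tag, paste0(path, ".prj"))
  invisible(path)
}

#' Read and write point sets as CSV
#'
#' Columns: `species`, `x`, `y`, `label`.
#'
#' @param path CSV path.
#' @return For `read_points`, a point-set data frame.
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "x", "y", "label")
  if (!all(req %in% names(df)))
    stop("point CSV must have columns: ", paste(req, collapse = ", "))
  point_set(df$species, df$x, df$y, df$label)
}

#' @param points A point-set data frame.
#' @rdname read_points
#' @export
write_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Minimal GeoJSON I/O for trails, regions and parks
#'
#' Reads a GeoJSON FeatureCollection into a list of features, each with
#' `geometry_type`, `coordinates` (a matrix, or list of matrices for Multi*
#' types and polygon rings), and `properties` (a named list). Only
#' LineString, MultiLineString, Polygon and Point are handled; that is all
#' the pipeline emits.
#'
#' @param path GeoJSON path.
#' @return List of features.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  lapply(gj$features, function(f) {
    geom <- f$geometry
    coords <- switch(geom$type,
      Point = matrix(unlist(geom$coordinates), ncol = 2),
      LineString = do.call(rbind, lapply(geom$coordinates, unlist)),
      MultiLineString = lapply(geom$coordinates, function(part)
        do.call(rbind, lapply(part, unlist))),
      Polygon = lapply(geom$coordinates, function(ring)
        do.call(rbind, lapply(ring, unlist))),
      stop("unsupported GeoJSON geometry: ", geom$type)
    )
    list(geometry_type = geom$type, coordinates = coords,
         properties = lapply(f$properties, function(p) p))
  })
}

#' @param features List of features as returned by [read_geojson()].
#' @rdname read_geojson
#' @export
write_geojson <- function(features, path) {
  fs <- lapply(features, function(f) {
    coords <- switch(f$geometry_type,
      Point = as.numeric(f$coordinates),
      LineString = apply(unname(f$coordinates), 1, as.numeric, simplify = FALSE),
      MultiLineString = lapply(f$coordinates, function(part)
        apply(unname(part), 1, as.numeric, simplify = FALSE)),
      Polygon = lapply(f$coordinates, function(ring)
        apply(unname(ring), 1, as.numeric, simplify = FALSE)),
      stop("unsupported geometry: ", f$geometry_type)
    )
    list(type = "Feature",
         geometry = list(type = f$geometry_type, coordinates = coords),
         properties = if (length(f$properties)) f$properties else
           structure(list(), names = character()))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = fs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Polyline features from coordinate matrices
#'
#' @param lines List of two-column coordinate matrices.
#' @param ids Optional feature ids.
#' @export
lines_to_features <- function(lines, ids = seq_along(lines)) {
  Map(function(m, id) list(geometry_type = "LineString", coordinates = m,
                           properties = list(id = id)),
      lines, ids)
}
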