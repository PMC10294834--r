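#' Thin presence points to one per pixel
#'
#' Survey records cluster; to avoid pseudo-replication at the analysis
#' resolution, at most one presence is retained per pixel. When several
#' points share a pixel, one is chosen uniformly at random under `seed`
#' (survey record order carries no meaning). Output is ordered by row-major
#' pixel index, so the result is deterministic given (points, spec, seed).
#'
#' @param points Presence point set (single species, `label == 1`).
#' @param spec The analysis [grid_spec()].
#' @param seed Integer seed for the tie-breaks.
#' @return Thinned point set.
#' @export
thin_to_pixel <- function(points, spec, seed = 1L) {
  stopifnot(all(points$label == 1), length(unique(points$species)) <= 1)
  if (nrow(points) == 0) return(points)
  rc <- xy_to_rowcol(spec, points$x, points$y)
  if (anyNA(rc[, 1])) stop("presence points outside the grid extent")
  pix <- (rc[, "row"] - 1) * spec$n_cols + rc[, "col"]
  keep <- with_seed(seed, {
    vapply(split(seq_len(nrow(points)), pix), function(ix) {
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
    }, integer(1))
  })
  keep <- keep[order(as.numeric(names(keep)))]
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample pseudo-absence background points
#'
#' Draws `n` cells uniformly without replacement from the analyzable cells
#' of `mask` (value 1), excluding any cell that contains a presence point,
#' and places one label-0 point at each drawn cell's center. True absences
#' are unrecorded in survey data; these background points stand in for them.
#'
#' @param mask [grid_layer()] with 1 = analyzable land; 0/`NA` excluded.
#' @param n Number of points (>= 1).
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @param exclude Optional point set whose cells are ineligible (presences).
#' @param species Species tag for the output points.
#' @return Point set with `label = 0`.
#' @export
sample_pseudo_absences <- function(mask, n, seed = 1L, exclude = NULL,
                                   species = "background") {
  stopifnot(inherits(mask, "grid_layer"), n >= 1)
  s <- mask$spec
  elig <- which(!is.na(mask$values) & mask$values == 1)
  if (!is.null(exclude) && nrow(exclude)) {
    rc <- xy_to_rowcol(s, exclude$x, exclude$y)
    ok <- !is.na(rc[, 1])
    occupied <- unique((rc[ok, "col"] - 1) * s$n_rows + rc[ok, "row"])
    elig <- setdiff(elig, occupied)
  }
  if (length(elig) < n)
    stop("only ", length(elig), " eligible cells for ", n,
         " pseudo-absences (short by ", n - length(elig), ")")
  drawn <- with_seed(seed, elig[sample.int(length(elig), n)])
  row <- ((drawn - 1) %% s$n_rows) + 1
  col <- ((drawn - 1) %/% s$n_rows) + 1
  ctr <- cell_center(s, row, col)
  point_set(species, ctr[, "x"], ctr[, "y"], 0)
}
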