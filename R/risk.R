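#' Union of binary species habitat maps
#'
#' Cell-wise logical OR: the composite potential-habitat map is 1 wherever
#' at least one species' binary map is 1. A cell is nodata only where every
#' input is nodata.
#'
#' @param maps List of binary [grid_layer()]s on one geometry.
#' @return Binary [grid_layer()].
#' @export
union_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]$spec
  acc <- matrix(NA_real_, ref$n_rows, ref$n_cols)
  for (m in maps) {
    if (!spec_equal(m$spec, ref)) stop("binary maps are on different grids")
    v <- m$values
    acc <- ifelse(is.na(acc), v, ifelse(is.na(v), acc, pmax(acc, v)))
  }
  grid_layer(acc, ref)
}

#' Snakebite incidence per 10,000 residents
#'
#' @param count Annual patient count (>= 0).
#' @param population Resident population (> 0).
#' @param digits Rounding for reporting; `NULL` returns full precision.
#' @return Incidence per 10,000 people.
#' @export
incidence_per_10k <- function(count, population, digits = NULL) {
  if (any(population <= 0)) stop("population must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  r <- 1e4 * count / population
  if (is.null(digits)) r else round(r, digits)
}

#' Habitat proportion per region
#'
#' @param union Binary habitat [grid_layer()].
#' @param regions Integer-label [grid_layer()] (0 = background).
#' @return Data frame `id`, `cells`, `habitat_cells`, `proportion`; regions
#'   whose cells are all nodata in the union get `NA`.
#' @export
regional_habitat_proportion <- function(union, regions) {
  stopifnot(spec_equal(union$spec, regions$spec))
  lab <- as.vector(regions$values)
  hab <- as.vector(union$values)
  keep <- !is.na(lab) & lab > 0 & !is.na(hab)
  ids <- sort(unique(lab[!is.na(lab) & lab > 0]))
  cells <- vapply(ids, function(i) sum(keep & lab == i), numeric(1))
  habs <- vapply(ids, function(i) sum(hab[keep & lab == i]), numeric(1))
  data.frame(id = ids, cells = cells, habitat_cells = habs,
             proportion = ifelse(cells > 0, habs / cells, NA_real_))
}

#' Spearman rank correlation test
#'
#' Rho is the Pearson correlation of mid-ranks. The p-value uses the
#' t-approximation with n-2 degrees of freedom (two-sided) — adequate at the
#' regional n of this analysis and documented as approximate — or exact full
#' permutation enumeration for n <= 8 when `method = "permutation"`.
#'
#' @param x,y Paired numeric vectors, n >= 4, no missing values.
#' @param method `"t"` (default) or `"permutation"` (n <= 8).
#' @return List `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero variance in ranks")
  rho <- stats::cor(rx, ry)
  if (method == "permutation") {
    if (n > 8) stop("exact permutation enumeration is limited to n <= 8")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1 - 1e-15) {
      p <- .Machine$double.xmin
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- max(2 * stats::pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
    }
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# All permutations of 1..n as rows (n small).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, matrix(c(seq_len(n))[-k][sub], nrow(sub)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Fraction of trail cells overlapping habitat within a zone
#'
#' Trails are evaluated cell-wise at the analysis resolution (each cell a
#' 30 m trail section under the defaults): the fraction of trail cells
#' inside `zone` that fall on habitat.
#'
#' @param union Binary habitat [grid_layer()].
#' @param trail_mask Binary trail [grid_layer()] (from [rasterize_lines()]).
#' @param zone_mask Optional binary zone [grid_layer()] (e.g., one park);
#'   `NULL` evaluates all trail cells.
#' @return Fraction in `[0, 1]`, or `NA` with a warning when the zone
#'   contains no trail cells.
#' @export
trail_overlap <- function(union, trail_mask, zone_mask = NULL) {
  stopifnot(spec_equal(union$spec, trail_mask$spec))
  tr <- !is.na(trail_mask$values) & trail_mask$values == 1
  if (!is.null(zone_mask)) {
    stopifnot(spec_equal(union$spec, zone_mask$spec))
    tr <- tr & !is.na(zone_mask$values) & zone_mask$values == 1
  }
  tr <- tr & !is.na(union$values)
  if (!any(tr)) {
    warning("no trail cells in zone; overlap undefined")
    return(NA_real_)
  }
  sum(union$values[tr] == 1) / sum(tr)
}

#' Habitat ratio of a park
#'
#' @param union Binary habitat [grid_layer()].
#' @param park_mask Binary park [grid_layer()] with at least one cell = 1.
#' @return Habitat cells within the park / park cells.
#' @export
park_risk_ratio <- function(union, park_mask) {
  stopifnot(spec_equal(union$spec, park_mask$spec))
  pk <- !is.na(park_mask$values) & park_mask$values == 1 & !is.na(union$values)
  if (!any(pk)) stop("park mask contains no valid cells")
  sum(union$values[pk] == 1) / sum(pk)
}

#' Mean land-cover scores over habitat cells
#'
#' @param union Binary habitat [grid_layer()].
#' @param cover_layers [predictor_stack()] of percent-cover grids (0-100).
#' @return Named numeric vector: mean percent per layer over `union == 1`
#'   cells; `NA` with a warning when there is no habitat.
#' @export
cover_composition <- function(union, cover_layers) {
  stopifnot(spec_equal(union$spec, cover_layers$spec))
  hab <- !is.na(union$values) & union$values == 1
  if (!any(hab)) {
    warning("no habitat cells; composition undefined")
    return(stats::setNames(rep(NA_real_, length(cover_layers$names)),
                           cover_layers$names))
  }
  vapply(cover_layers$layers, function(g) mean(g$values[hab], na.rm = TRUE),
         numeric(1))
}

#' Assemble the per-region risk table
#'
#' Joins regional habitat proportions, populations and incident counts into
#' one table: cells, area (km^2 under meter map units), incidence per
#' 10,000 (2-decimal reporting column plus full precision), habitat
#' proportion, and optionally trail overlap per region.
#'
#' @param union Binary habitat [grid_layer()].
#' @param regions Integer-label [grid_layer()] of region ids.
#' @param region_info Data frame `id`, `name`, `population`, `snakebites`.
#' @param trail_mask Optional binary trail [grid_layer()].
#' @return Data frame, one row per region.
#' @export
build_region_table <- function(union, regions, region_info,
                               trail_mask = NULL) {
  stopifnot(all(c("id", "name", "population", "snakebites") %in%
                  names(region_info)))
  hp <- regional_habitat_proportion(union, regions)
  out <- merge(region_info, hp, by = "id", all.x = TRUE)
  out$area_km2 <- cell_area(out$cells, union$spec)
  out$incidence_per_10k <- incidence_per_10k(out$snakebites, out$population)
  out$incidence_per_10k_2dp <- round(out$incidence_per_10k, 2)
  names(out)[names(out) == "proportion"] <- "habitat_proportion"
  if (!is.null(trail_mask)) {
    lab <- as.vector(regions$values)
    tr <- as.vector(trail_mask$values)
    habv <- as.vector(union$values)
    out$trail_cells <- vapply(out$id, function(i)
      sum(tr == 1 & lab == i, na.rm = TRUE), numeric(1))
    out$trail_habitat_overlap <- vapply(out$id, function(i) {
      sel <- !is.na(tr) & tr == 1 & !is.na(lab) & lab == i & !is.na(habv)
      if (!any(sel)) NA_real_ else sum(habv[sel] == 1) / sum(sel)
    }, numeric(1))
  }
  out[order(out$id), ]
}

#' Table of reported regional snakebite statistics
#'
#' The published 2016 regional summary shipped with the package: region ids
#' and names, populations (millions), areas, snakebite counts and the
#' printed per-10,000 incidence, for the 16 mainland regions.
#'
#' @return Data frame with columns `id`, `region`, `population_millions`,
#'   `area_km2`, `snakebites`, `per_10k_printed`.
#' @export
snakebite_regions <- function() {
  utils::read.csv(system.file("extdata", "snakebite_regions_2016.csv",
                              package = "sdmrisk"),
                  stringsAsFactors = FALSE)
}

#' Reported per-species variable importance
#'
#' The published mean-decrease-Gini importance per environmental variable
#' for the three species models, with the printed across-species median.
#'
#' @return Data frame `variable`, `G_brevicaudus`, `G_ussuriensis`,
#'   `G_saxatilis`, `median_printed`.
#' @export
reported_mdg <- function() {
  utils::read.csv(system.file("extdata", "mdg_importance.csv",
                              package = "sdmrisk"),
                  stringsAsFactors = FALSE)
}
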