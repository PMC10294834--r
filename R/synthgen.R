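# Smooth correlated Gaussian random field on an n_rows x n_cols grid:
# white noise spectrally filtered with a Gaussian low-pass of correlation
# length `smoothness` (in cells); smoothness 0 returns white noise.
# Standardized to mean 0, sd 1 (sd 1 guaranteed only for smoothness < dim).
smooth_field <- function(n_rows, n_cols, smoothness, seed) {
  noise <- with_seed(seed, matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols))
  if (smoothness <= 0) return(noise)
  fr <- (seq_len(n_rows) - 1) / n_rows; fr[fr > 0.5] <- fr[fr > 0.5] - 1
  fc <- (seq_len(n_cols) - 1) / n_cols; fc[fc > 0.5] <- fc[fc > 0.5] - 1
  H <- exp(-0.5 * smoothness^2 * (outer(fr^2, fc^2, `+`)) * (2 * pi)^2)
  f <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / (n_rows * n_cols)
  (f - mean(f)) / stats::sd(f)
}

#' Species response parameters
#'
#' Parameterizes a species' true suitability on the synthetic landscape:
#' a logistic model with a negative TPI coefficient (valley preference), a
#' Gaussian bump in slope centered at the species' optimum, a
#' plateau-with-logistic-shoulders temperature window, and optionally a weak
#' linear herbaceous-cover term.
#'
#' @param name Species tag.
#' @param temp_window Numeric `(low, high)` in deg C; suitability is high
#'   inside, falling off over `temp_shoulder` degrees at each edge.
#' @param tpi_coefficient Logit units per TPI meter; < 0 prefers valleys.
#' @param slope_optimum,slope_width Degrees: center and SD of the slope bump.
#' @param baseline_logit Intercept.
#' @param slope_amplitude,temp_amplitude Logit heights of the slope bump and
#'   temperature plateau.
#' @param temp_shoulder Logistic shoulder scale (deg C).
#' @param herb_coefficient Logit units per percent herbaceous cover.
#' @return A `species_params` list.
#' @export
species_params <- function(name, temp_window, tpi_coefficient = -0.3,
                           slope_optimum = 15, slope_width = 8,
                           baseline_logit = -9, slope_amplitude = 4,
                           temp_amplitude = 5.5, temp_shoulder = 0.5,
                           herb_coefficient = 0.09) {
  stopifnot(temp_window[1] < temp_window[2], slope_width > 0,
            tpi_coefficient < 0)
  structure(list(name = name, temp_window = temp_window,
                 tpi_coefficient = tpi_coefficient,
                 slope_optimum = slope_optimum, slope_width = slope_width,
                 baseline_logit = baseline_logit,
                 slope_amplitude = slope_amplitude,
                 temp_amplitude = temp_amplitude,
                 temp_shoulder = temp_shoulder,
                 herb_coefficient = herb_coefficient),
            class = "species_params")
}

#' Configuration of a synthetic study system
#'
#' Defaults define the study conditions the generator emulates: a 256 x 256
#' grid of 30 m cells (~59 km^2), elevations 0-1200 m with a 25-cell
#' correlation length, temperature tied to elevation by a 6.5 deg C/km lapse
#' rate with smooth noise weak enough that |r(temperature, elevation)| >
#' 0.75, an engineered herbaceous-shrubland collinear pair, three species
#' with valley/slope/temperature-window responses (700 / 1500 / 100
#' presences, mirroring the real survey's counts at this grid's scale),
#' 2000 pseudo-absences, 16 regions with Poisson incidents whose rate rises
#' with habitat proportion, 8 valley-biased trails and 3 parks.
#'
#' @param n_rows,n_cols,cell_size Grid geometry (meters).
#' @param seed Master seed; all stage seeds derive from it.
#' @param dem_smoothness Correlation length of the DEM field, in cells.
#' @param dem_roughness Weight (0-1) of the fine-scale relief component.
#' @param elev_range Elevation range (m).
#' @param t0 Sea-level temperature (deg C); `lapse` in deg C per km.
#' @param temp_noise_sd SD of the smooth temperature noise, expressed as a
#'   fraction of the lapse signal's SD (0.62 puts the engineered
#'   temperature-elevation correlation near 0.85 on any landscape).
#' @param precip_range Precipitation range (mm).
#' @param species List of [species_params()].
#' @param n_presence Named presence counts per species.
#' @param n_pseudo Pseudo-absence count.
#' @param k_regions Number of regions; `pop_range` log-uniform bounds;
#'   `incident_a`/`incident_b` intercept and slope of the per-10k rate in
#'   habitat proportion.
#' @param n_trails,trail_steps,n_parks Vector-feature counts.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_rows = 256, n_cols = 256, cell_size = 30,
                         seed = 1L,
                         dem_smoothness = 25, dem_roughness = 0.2,
                         elev_range = c(0, 1200),
                         t0 = 22, lapse = 6.5, temp_noise_sd = 0.62,
                         precip_range = c(900, 1600),
                         species = list(
                           species_params("G_brevicaudus", c(18, 20)),
                           species_params("G_ussuriensis", c(14, 19)),
                           species_params("G_saxatilis", c(14, 17.5))),
                         n_presence = c(G_brevicaudus = 700,
                                        G_ussuriensis = 1500,
                                        G_saxatilis = 100),
                         n_pseudo = 2000,
                         k_regions = 16, pop_range = c(1e5, 1e7),
                         incident_a = 0.1, incident_b = 4,
                         n_trails = 8, trail_steps = 200, n_parks = 3) {
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic DEM
#'
#' A two-scale spectrally filtered Gaussian random field — broad structure
#' at correlation length `dem_smoothness` plus a `dem_roughness` fraction of
#' fine-scale relief — rescaled to `elev_range`. The fine component gives
#' the terrain realistic local relief, so 30 m TPI and slope have the
#' variability the species responses act on. Deterministic given the
#' config's seed.
#'
#' @param config A [synth_config()].
#' @return Elevation [grid_layer()] in meters.
#' @export
gen_dem <- function(config) {
  w2 <- config$dem_roughness
  f <- (1 - w2) * smooth_field(config$n_rows, config$n_cols,
                               config$dem_smoothness, config$seed + 11L)
  if (w2 > 0)
    f <- f + w2 * smooth_field(config$n_rows, config$n_cols, 3,
                               config$seed + 12L)
  z <- (f - min(f)) / (max(f) - min(f))
  z <- config$elev_range[1] + z * diff(config$elev_range)
  grid_layer(z, grid_spec(config$n_rows, config$n_cols, config$cell_size))
}

#' Generate climate layers tied to the DEM
#'
#' Temperature is a lapse-rate function of elevation plus smooth noise; the
#' noise is weak enough that |pearson(temperature, elevation)| > 0.75 (the
#' collinearity the screening stage must detect). Checked after each draw
#' and redrawn up to 5 times; failure errors with advice to reduce
#' `temp_noise_sd`. Precipitation is an independent smooth field.
#'
#' @param dem Elevation [grid_layer()].
#' @param config A [synth_config()].
#' @return List of `temperature` and `precipitation` [grid_layer()]s.
#' @export
gen_climate <- function(dem, config) {
  s <- dem$spec
  signal_sd <- stats::sd(config$lapse * dem$values / 1000)
  for (attempt in 1:5) {
    noise <- smooth_field(s$n_rows, s$n_cols, 10,
                          config$seed + 23L + attempt) *
      config$temp_noise_sd * signal_sd
    temp <- config$t0 - config$lapse * dem$values / 1000 + noise
    if (abs(stats::cor(as.vector(temp), as.vector(dem$values))) > 0.75) {
      pf <- smooth_field(s$n_rows, s$n_cols, config$dem_smoothness,
                         config$seed + 31L)
      pz <- (pf - min(pf)) / (max(pf) - min(pf))
      precip <- config$precip_range[1] + pz * diff(config$precip_range)
      return(list(temperature = grid_layer(temp, s),
                  precipitation = grid_layer(precip, s)))
    }
  }
  stop("could not reach |r(temperature, elevation)| > 0.75; ",
       "reduce temp_noise_sd")
}

#' Generate percent land-cover layers
#'
#' Four smooth percent-cover fields clipped to [0, 100]; shrubland is a
#' monotone function of herbaceous plus small noise so the pair's |r|
#' exceeds 0.75 (the second engineered collinear pair).
#'
#' @param config A [synth_config()].
#' @return List of `bare`, `herbaceous`, `shrubland`, `forest` layers.
#' @export
gen_covers <- function(config) {
  s <- grid_spec(config$n_rows, config$n_cols, config$cell_size)
  clip01 <- function(m) pmin(pmax(m, 0), 100)
  herb0 <- smooth_field(config$n_rows, config$n_cols, 8, config$seed + 41L)
  for (attempt in 1:5) {
    herb <- clip01(45 + 20 * herb0)
    shrub <- clip01(10 + 0.75 * herb +
                      9 * smooth_field(config$n_rows, config$n_cols, 8,
                                       config$seed + 43L + attempt))
    if (abs(stats::cor(as.vector(herb), as.vector(shrub))) > 0.75) break
    if (attempt == 5) stop("herbaceous/shrubland correlation did not reach 0.75")
  }
  forest <- clip01(60 + 20 * smooth_field(config$n_rows, config$n_cols, 15,
                                          config$seed + 47L))
  bare <- clip01(20 + 12 * smooth_field(config$n_rows, config$n_cols, 12,
                                        config$seed + 53L))
  list(bare = grid_layer(bare, s), herbaceous = grid_layer(herb, s),
       shrubland = grid_layer(shrub, s), forest = grid_layer(forest, s))
}

#' True suitability surface for one species
#'
#' `plogis(baseline + tpi_coefficient * TPI + slope bump + temperature
#' window [+ herb_coefficient * herbaceous])` — the response shapes the
#' species models should recover: valley preference (TPI < 0), a slope
#' optimum near 15 degrees, and a species-specific temperature window.
#'
#' @param stack [predictor_stack()] containing `tpi`, `slope`,
#'   `temperature` (and `herbaceous` when `herb_coefficient != 0`).
#' @param params A [species_params()].
#' @return Probability [grid_layer()] in (0, 1).
#' @export
true_suitability <- function(stack, params) {
  need <- c("tpi", "slope", "temperature",
            if (params$herb_coefficient != 0) "herbaceous")
  missing <- setdiff(need, stack$names)
  if (length(missing))
    stop("stack is missing layer(s): ", paste(missing, collapse = ", "))
  tpi <- stack$layers$tpi$values
  slope <- stack$layers$slope$values
  temp <- stack$layers$temperature$values
  w <- stats::plogis((temp - params$temp_window[1]) / params$temp_shoulder) *
    stats::plogis((params$temp_window[2] - temp) / params$temp_shoulder)
  eta <- params$baseline_logit +
    params$tpi_coefficient * tpi +
    params$slope_amplitude *
      exp(-(slope - params$slope_optimum)^2 / (2 * params$slope_width^2)) +
    params$temp_amplitude * w
  if (params$herb_coefficient != 0)
    eta <- eta + params$herb_coefficient * stack$layers$herbaceous$values
  grid_layer(stats::plogis(eta), stack$spec)
}

#' Sample presence points from a suitability surface
#'
#' Draws `n` distinct cells with probability proportional to suitability
#' (weighted sampling without replacement) and places a presence at each
#' drawn cell's center — a stand-in for survey occurrence records.
#'
#' @param suitability Probability [grid_layer()].
#' @param n Number of presences (<= number of valid cells).
#' @param seed Integer seed.
#' @param species Species tag.
#' @return Presence point set (`label = 1`).
#' @export
sample_presences <- function(suitability, n, seed = 1L, species = "species") {
  s <- suitability$spec
  p <- as.vector(suitability$values)
  ok <- which(!is.na(p) & p > 0)
  if (n > length(ok)) stop("n = ", n, " exceeds ", length(ok), " valid cells")
  drawn <- with_seed(seed, ok[sample.int(length(ok), n, prob = p[ok])])
  row <- ((drawn - 1) %% s$n_rows) + 1
  col <- ((drawn - 1) %/% s$n_rows) + 1
  ctr <- cell_center(s, row, col)
  point_set(species, ctr[, "x"], ctr[, "y"], 1)
}

#' Generate regions, populations and Poisson incident counts
#'
#' Tiles the grid into `k_regions` rectangles, draws log-uniform
#' populations, computes each region's true habitat proportion from
#' `habitat_union`, and draws incident counts from
#' `Poisson(population * (a + b * proportion) / 1e4)`, so the expected
#' per-10k incidence rises linearly in habitat proportion when `b > 0`.
#'
#' @param habitat_union Binary habitat [grid_layer()].
#' @param config A [synth_config()] (fields `k_regions`, `pop_range`,
#'   `incident_a`, `incident_b`).
#' @param seed Integer seed (defaults to the config's).
#' @return List: `region_grid` (integer labels), `regions` (data frame
#'   `id`, `name`, `population`, `snakebites`, `true_proportion`), and the
#'   generating `a`, `b`.
#' @export
gen_regions_and_incidents <- function(habitat_union, config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 61L
  k <- config$k_regions
  stopifnot(k >= 4)
  s <- habitat_union$spec
  kr <- floor(sqrt(k))
  while (k %% kr != 0) kr <- kr - 1
  kc <- k %/% kr
  row_band <- pmin(ceiling(seq_len(s$n_rows) / (s$n_rows / kr)), kr)
  col_band <- pmin(ceiling(seq_len(s$n_cols) / (s$n_cols / kc)), kc)
  lab <- outer(row_band, col_band, function(r, c) (r - 1) * kc + c)
  region_grid <- grid_layer(lab, s)
  props <- regional_habitat_proportion(habitat_union, region_grid)
  out <- with_seed(seed, {
    pop <- round(10^stats::runif(k, log10(config$pop_range[1]),
                                 log10(config$pop_range[2])))
    rate <- config$incident_a + config$incident_b * props$proportion
    cnt <- stats::rpois(k, pop * rate / 1e4)
    data.frame(id = props$id, name = paste0("region_", props$id),
               population = pop, snakebites = cnt,
               true_proportion = props$proportion)
  })
  list(region_grid = region_grid, regions = out,
       a = config$incident_a, b = config$incident_b)
}

#' Generate hiking trails and park polygons
#'
#' Trails are seeded random walks over the 8-neighborhood, biased toward
#' descending TPI (valley following, as real trails tend to be); parks are
#' random axis-aligned rectangles of at least 100 cells.
#'
#' @param tpi TPI [grid_layer()] used for the valley bias.
#' @param config A [synth_config()] (`n_trails`, `trail_steps`, `n_parks`).
#' @param seed Integer seed (defaults to the config's).
#' @param valley_bias Softmax inverse-temperature on -TPI; 0 removes the
#'   bias.
#' @return List: `trails` (list of coordinate matrices), `parks` (list of
#'   closed polygon rings).
#' @export
gen_trails_and_parks <- function(tpi, config, seed = NULL, valley_bias = 2) {
  if (is.null(seed)) seed <- config$seed + 71L
  s <- tpi$spec
  tpi_sd <- stats::sd(tpi$values, na.rm = TRUE)
  nbr <- expand.grid(dr = -1:1, dc = -1:1)
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  with_seed(seed, {
    trails <- lapply(seq_len(config$n_trails), function(i) {
      r <- sample.int(s$n_rows, 1); c <- sample.int(s$n_cols, 1)
      path <- matrix(NA_real_, config$trail_steps + 1, 2)
      path[1, ] <- cell_center(s, r, c)
      for (step in seq_len(config$trail_steps)) {
        rr <- r + nbr$dr; cc <- c + nbr$dc
        ok <- rr >= 1 & rr <= s$n_rows & cc >= 1 & cc <= s$n_cols
        rr <- rr[ok]; cc <- cc[ok]
        tv <- tpi$values[cbind(rr, cc)]
        tv[is.na(tv)] <- 0
        wgt <- exp(-valley_bias * tv / max(tpi_sd, 1e-9))
        j <- sample.int(length(rr), 1, prob = wgt)
        r <- rr[j]; c <- cc[j]
        path[step + 1, ] <- cell_center(s, r, c)
      }
      path
    })
    parks <- lapply(seq_len(config$n_parks), function(i) {
      w <- sample(10:25, 1); h <- sample(10:25, 1)
      c0 <- sample.int(s$n_cols - w, 1); r0 <- sample.int(s$n_rows - h, 1)
      x0 <- s$origin_x + (c0 - 1) * s$cell_size
      y0 <- s$origin_y - (r0 - 1) * s$cell_size
      rbind(c(x0, y0), c(x0 + w * s$cell_size, y0),
            c(x0 + w * s$cell_size, y0 - h * s$cell_size),
            c(x0, y0 - h * s$cell_size), c(x0, y0))
    })
    list(trails = trails, parks = parks)
  })
}

#' Generate a complete synthetic study system
#'
#' Runs every generator stage and assembles the candidate predictor stack
#' (elevation, tpi, slope, temperature, precipitation, bare, herbaceous,
#' shrubland, forest — elevation and shrubland included deliberately so the
#' screening stage has its engineered collinear pairs to find), per-species
#' true suitability surfaces and presence points, a land mask, trails and
#' parks. Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param tpi_radius Neighborhood radius for the TPI layer.
#' @return List: `config`, `stack`, `mask`, `suitability` (per species),
#'   `presences` (per species), `trails`, `parks`.
#' @export
gen_study_system <- function(config = synth_config(), tpi_radius = 1) {
  dem <- gen_dem(config)
  tpi <- terrain_tpi(dem, radius = tpi_radius)
  slope <- terrain_slope(dem)
  clim <- gen_climate(dem, config)
  covers <- gen_covers(config)
  stack <- predictor_stack(c(
    list(elevation = dem, tpi = tpi, slope = slope,
         temperature = clim$temperature,
         precipitation = clim$precipitation),
    covers))
  mask <- grid_layer(matrix(1, config$n_rows, config$n_cols), stack$spec)
  suit <- list(); pres <- list()
  for (i in seq_along(config$species)) {
    sp <- config$species[[i]]
    suit[[sp$name]] <- true_suitability(stack, sp)
    pres[[sp$name]] <- sample_presences(
      suit[[sp$name]], config$n_presence[[sp$name]],
      seed = config$seed + 100L + 7L * i, species = sp$name)
  }
  tp <- gen_trails_and_parks(tpi, config)
  list(config = config, stack = stack, mask = mask,
       suitability = suit, presences = pres,
       trails = tp$trails, parks = tp$parks)
}
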