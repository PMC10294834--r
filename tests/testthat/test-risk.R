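test_that("union of binary maps is a cell-wise OR with nodata only where all miss", {
  a <- mk_grid(matrix(c(0, 1, NA, 0), 2))
  b <- mk_grid(matrix(c(1, 0, 1, NA), 2))
  u <- union_maps(list(a, b))
  expect_equal(u$values, matrix(c(1, 1, 1, 0), 2))
  expect_true(is.na(union_maps(list(a, a))$values[1, 2]))
  expect_error(union_maps(list(a, mk_grid(matrix(0, 3, 3)))), "different grids")

  for (seed in 1:20) {
    maps <- with_seed(seed, lapply(1:3, function(i)
      mk_grid(matrix(rbinom(100, 1, 0.3), 10))))
    u <- union_maps(maps)
    oracle <- matrix(pmax(maps[[1]]$values, maps[[2]]$values,
                          maps[[3]]$values), 10)
    expect_identical(u$values, oracle)
    areas <- vapply(maps, function(m) sum(m$values), numeric(1))
    expect_gte(sum(u$values), max(areas))
    expect_lte(sum(u$values), sum(areas))
  }
})

test_that("incidence per 10,000 reproduces the published regional rates", {
  expect_equal(incidence_per_10k(316, 1.55e6, digits = 2), 2.04)
  expect_equal(incidence_per_10k(569, 2.70e6, digits = 2), 2.11)
  expect_equal(incidence_per_10k(0, 5e5), 0)
  expect_error(incidence_per_10k(10, 0), "positive")
  expect_error(incidence_per_10k(-1, 100), "non-negative")
})

test_that("regional habitat proportions match masked counting", {
  union <- mk_grid(matrix(c(1, 1, 0, 0), 2))
  regions <- mk_grid(matrix(c(1, 1, 2, 2), 2))
  hp <- regional_habitat_proportion(union, regions)
  expect_equal(hp$proportion, c(1, 0))

  for (seed in 1:10) {
    u <- with_seed(seed, mk_grid(matrix(rbinom(144, 1, 0.4), 12)))
    r <- mk_grid(matrix(rep(1:4, each = 36), 12))
    hp <- regional_habitat_proportion(u, r)
    for (id in 1:4) {
      sel <- r$values == id
      expect_equal(hp$proportion[hp$id == id],
                   sum(u$values[sel]) / sum(sel))
    }
  }
})

test_that("Spearman test matches the direct rank-Pearson computation", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_test(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_test(x, -x)$rho, -1)

  for (seed in 1:20) {
    d <- with_seed(seed, list(x = round(rnorm(16), 1), y = round(rnorm(16), 1)))
    got <- spearman_test(d$x, d$y)
    expect_equal(got$rho, stats::cor(rank(d$x), rank(d$y)), tolerance = 1e-12)
    expect_equal(got$rho,
                 suppressWarnings(stats::cor.test(d$x, d$y,
                                                  method = "spearman"))$estimate[[1]],
                 tolerance = 1e-12)
    expect_gt(got$p_value, 0)
    expect_lte(got$p_value, 1)
  }
  expect_error(spearman_test(rep(1, 5), 1:5), "zero variance")
  expect_error(spearman_test(1:3, 3:1), "at least 4")
})

test_that("exact permutation p agrees with the reference distribution at small n", {
  d <- with_seed(3, list(x = rnorm(6), y = rnorm(6)))
  got <- spearman_test(d$x, d$y, method = "permutation")
  # reference: exact p from the classical algorithm (no ties at random reals)
  ref <- stats::cor.test(d$x, d$y, method = "spearman", exact = TRUE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-12)
  expect_error(spearman_test(rnorm(12), rnorm(12), method = "permutation"),
               "n <= 8")
})

test_that("trail overlap and park ratios are masked fractions", {
  union <- mk_grid(matrix(c(1, 1, 0, 0), 2))
  trail <- mk_grid(matrix(c(1, 0, 1, 0), 2))
  expect_equal(trail_overlap(union, trail), 0.5)
  all_in <- mk_grid(matrix(c(1, 1, 0, 0), 2))
  expect_equal(trail_overlap(union, all_in), 1)
  empty_hab <- mk_grid(matrix(0, 2, 2))
  expect_equal(trail_overlap(empty_hab, trail), 0)
  zone0 <- mk_grid(matrix(0, 2, 2))
  expect_warning(ov <- trail_overlap(union, trail, zone0), "no trail cells")
  expect_true(is.na(ov))

  park <- mk_grid(matrix(1, 2, 2))
  expect_equal(park_risk_ratio(union, park), 0.5)
  expect_equal(park_risk_ratio(mk_grid(matrix(1, 2, 2)), park), 1)
  expect_error(park_risk_ratio(union, zone0), "no valid cells")

  for (seed in 1:10) {
    u <- with_seed(seed, mk_grid(matrix(rbinom(100, 1, 0.5), 10)))
    tr <- with_seed(seed + 50, mk_grid(matrix(rbinom(100, 1, 0.2), 10)))
    zn <- with_seed(seed + 99, mk_grid(matrix(rbinom(100, 1, 0.6), 10)))
    denom <- sum(tr$values == 1 & zn$values == 1)
    if (denom == 0) next
    expect_equal(trail_overlap(u, tr, zn),
                 sum(u$values == 1 & tr$values == 1 & zn$values == 1) / denom)
  }
})

test_that("cover composition averages percent scores over habitat cells", {
  union <- mk_grid(matrix(c(1, 0, 1, 0), 2))
  covers <- predictor_stack(list(forest = mk_grid(matrix(80, 2, 2)),
                                 crop = mk_grid(matrix(c(100, 0, 100, 0), 2))))
  comp <- cover_composition(union, covers)
  expect_equal(comp[["forest"]], 80)
  expect_equal(comp[["crop"]], 100)
  expect_warning(c0 <- cover_composition(mk_grid(matrix(0, 2, 2)), covers),
                 "no habitat")
  expect_true(all(is.na(c0)))
})

test_that("adding a species map never decreases any overlay statistic", {
  for (seed in 1:10) {
    maps <- with_seed(seed, lapply(1:2, function(i)
      mk_grid(matrix(rbinom(400, 1, 0.25), 20))))
    regions <- mk_grid(matrix(rep(1:4, each = 100), 20))
    trail <- with_seed(seed + 7, mk_grid(matrix(rbinom(400, 1, 0.15), 20)))
    park <- mk_grid(matrix(rep(c(1, 0), c(100, 300)), 20))
    u1 <- union_maps(maps[1])
    u2 <- union_maps(maps)
    hp1 <- regional_habitat_proportion(u1, regions)
    hp2 <- regional_habitat_proportion(u2, regions)
    expect_true(all(hp2$proportion >= hp1$proportion))
    expect_gte(park_risk_ratio(u2, park), park_risk_ratio(u1, park))
    if (sum(trail$values) > 0)
      expect_gte(trail_overlap(u2, trail), trail_overlap(u1, trail))
    # region habitat cells partition the labelled total
    expect_equal(sum(hp2$habitat_cells), sum(u2$values))
  }
})

test_that("the region table assembles areas, rates and overlaps consistently", {
  union <- mk_grid(matrix(rep(c(1, 0), 50), 10), cell = 30)
  regions <- mk_grid(matrix(rep(1:2, each = 50), 10), cell = 30)
  trail <- mk_grid(matrix(rbinom(100, 1, 0.3), 10), cell = 30)
  info <- data.frame(id = 1:2, name = c("west", "east"),
                     population = c(1.55e6, 2.70e6),
                     snakebites = c(316, 569))
  tab <- build_region_table(union, regions, info, trail_mask = trail)
  expect_equal(tab$incidence_per_10k_2dp, c(2.04, 2.11))
  expect_equal(tab$area_km2, rep(50 * 900 / 1e6, 2))
  expect_equal(tab$habitat_proportion,
               regional_habitat_proportion(union, regions)$proportion)
  expect_true(all(tab$trail_habitat_overlap >= 0 &
                    tab$trail_habitat_overlap <= 1, na.rm = TRUE))
})
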