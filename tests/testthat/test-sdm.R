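test_that("train/test split is stratified, rounded, and seed-reproducible", {
  d <- data.frame(label = rep(c(0, 1), each = 100), x = rnorm(200))
  s <- split_train_test(d, seed = 1)
  expect_equal(sum(s$split == "train" & s$label == 1), 70)
  expect_equal(sum(s$split == "train" & s$label == 0), 70)

  expect_identical(split_train_test(d, seed = 5)$split,
                   split_train_test(d, seed = 5)$split)
  expect_false(identical(split_train_test(d, seed = 5)$split,
                         split_train_test(d, seed = 6)$split))

  d703 <- data.frame(label = c(rep(1, 703), rep(0, 300)), x = rnorm(1003))
  n_tr <- sum(split_train_test(d703, seed = 2)$split == "train" &
                d703$label == 1)
  expect_true(n_tr %in% c(492, 493))

  expect_error(split_train_test(data.frame(label = c(1, 0, 0), x = 1:3)),
               "at least 2")
})

test_that("mtry tuning scans the doubling ladder and returns the OOB minimizer", {
  expect_equal(tune_mtry(data.frame(x = rnorm(50)), rbinom(50, 1, 0.5))$mtry,
               1L)

  d <- with_seed(3, {
    X <- as.data.frame(matrix(rnorm(400 * 4), ncol = 4))
    list(X = X, y = rbinom(400, 1, plogis(rowSums(X))))
  })
  tuned <- tune_mtry(d$X, d$y, n_trees = 100, seed = 9)
  cands <- as.integer(names(tuned$oob))
  expect_true(tuned$mtry %in% cands)
  expect_true(all(sdmrisk:::mtry_candidates(4) == c(1, 2, 4)))
  # returned candidate attains the minimal OOB error among all candidates,
  # recomputed directly
  direct <- vapply(cands, function(m) {
    fit <- with_seed(9 + m, randomForest::randomForest(
      x = d$X, y = factor(d$y, levels = c(0, 1)), ntree = 100, mtry = m))
    unname(fit$err.rate[100, "OOB"])
  }, numeric(1))
  expect_equal(unname(tuned$oob), direct)
  expect_equal(tuned$oob[[as.character(tuned$mtry)]], min(direct))

  noise <- with_seed(4, list(X = as.data.frame(matrix(rnorm(200 * 3), ncol = 3)),
                             y = rbinom(200, 1, 0.5)))
  expect_true(tune_mtry(noise$X, noise$y, n_trees = 50, seed = 1)$mtry %in%
                c(1L, 2L, 3L))
})

test_that("random forest separates separable data and is seed-deterministic", {
  d <- mk_separable(300)
  fit <- fit_rf(d[, c("x1", "x2")], d$label, n_trees = 200, seed = 1)
  expect_gte(roc_auc(rf_scores(fit, d[, c("x1", "x2")]), d$label), 0.99)
  fit2 <- fit_rf(d[, c("x1", "x2")], d$label, n_trees = 200, seed = 1)
  expect_identical(rf_scores(fit, d[, c("x1", "x2")]),
                   rf_scores(fit2, d[, c("x1", "x2")]))
  expect_error(fit_rf(d[, c("x1", "x2")], rep(1, 300)), "single class")
})

test_that("random forest is null-calibrated on pure-noise labels", {
  aucs <- vapply(1:20, function(seed) {
    d <- with_seed(seed, data.frame(x1 = rnorm(500), x2 = rnorm(500),
                                    label = rbinom(500, 1, 0.5)))
    s <- split_train_test(d, seed = seed)
    tr <- s$split == "train"
    fit <- fit_rf(s[tr, c("x1", "x2")], s$label[tr], n_trees = 100,
                  seed = seed)
    roc_auc(rf_scores(fit, s[!tr, c("x1", "x2")]), s$label[!tr])
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("duplicating every training row leaves predictions nearly unchanged", {
  d <- mk_separable(200, seed = 8)
  X <- d[, c("x1", "x2")]
  f1 <- fit_rf(X, d$label, n_trees = 500, seed = 3)
  f2 <- fit_rf(rbind(X, X), c(d$label, d$label), n_trees = 500, seed = 3)
  p1 <- rf_scores(f1, X); p2 <- rf_scores(f2, X)
  expect_lt(mean(abs(p1 - p2)), 0.05)
  expect_equal(roc_auc(p1, d$label), roc_auc(p2, d$label), tolerance = 0.01)
})

test_that("AUC follows the Mann-Whitney formulation with tied scores", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  for (seed in 1:10) {
    d <- with_seed(seed, list(s = round(runif(30), 1),
                              y = rbinom(30, 1, 0.5)))
    if (length(unique(d$y)) < 2) next
    expect_equal(roc_auc(d$s, d$y), auc_pairs(d$s, d$y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "single class")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  d <- with_seed(2, list(s = runif(100), y = rbinom(100, 1, 0.5)))
  a <- roc_auc(d$s, d$y)
  expect_equal(roc_auc(exp(3 * d$s), d$y), a)
  expect_equal(roc_auc(rank(d$s), d$y), a)
  expect_equal(roc_auc(qlogis(d$s), d$y), a)
})

test_that("threshold selection maximizes sens + spec over all candidate cuts", {
  r <- select_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$threshold, 0.5)
  expect_equal(r$sens + r$spec, 2)

  anti <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(anti$sens + anti$spec, 1)

  two <- select_threshold(c(0.7, 0.3), c(1, 0))
  expect_equal(two$threshold, 0.5)
  expect_equal(c(two$sens, two$spec), c(1, 1))

  # exhaustive optimality and smallest-threshold tie-break on 100 instances
  for (seed in 1:100) {
    d <- with_seed(seed, {
      n <- sample(5:200, 1)
      list(s = round(runif(n), sample(1:3, 1)),
           y = c(0, 1, rbinom(n - 2, 1, 0.5)))
    })
    got <- select_threshold(d$s, d$y)
    ref <- threshold_exhaustive(d$s, d$y)
    expect_equal(got$sens + got$spec, ref$best_sum, tolerance = 1e-9)
    expect_equal(got$threshold, ref$threshold)
  }
})

test_that("TSS is sensitivity plus specificity minus one", {
  expect_identical(tss(1, 1), 1)
  expect_identical(tss(0.5, 0.5), 0)
  expect_identical(tss(0.2, 0.3), -0.5)
  expect_error(tss(1.2, 0.5))
})

test_that("cross-validation is stratified and guards degenerate folds", {
  d <- mk_separable(200, seed = 5)
  cv <- cross_validate(d[, c("x1", "x2")], d$label, k = 10, seed = 1,
                       n_trees = 100, tune = FALSE)
  expect_length(cv$fold_auc, 10)
  expect_gte(cv$mean, 0.95)

  expect_error(cross_validate(d[, c("x1", "x2")], d$label, k = 101),
               "folds")
  expect_error(assign_folds(c(rep(1, 3), rep(0, 50)), k = 5), "folds")
})

test_that("cross-validated AUC is null-calibrated on noise labels", {
  means <- vapply(1:10, function(seed) {
    d <- with_seed(seed + 50, data.frame(x1 = rnorm(100), x2 = rnorm(100),
                                         label = rep(c(0, 1), 50)))
    cross_validate(d[, c("x1", "x2")], d$label, k = 5, seed = seed,
                   n_trees = 50, tune = FALSE)$mean
  }, numeric(1))
  expect_gt(mean(means), 0.4)
  expect_lt(mean(means), 0.6)
})

test_that("Gini importance separates signal from noise variables", {
  wins <- vapply(1:100, function(seed) {
    d <- with_seed(seed, {
      x1 <- rnorm(200)
      data.frame(x1 = x1, x2 = rnorm(200),
                 label = rbinom(200, 1, plogis(2 * x1)))
    })
    fit <- fit_rf(d[, c("x1", "x2")], d$label, n_trees = 50, seed = seed)
    imp <- gini_importance(fit)
    imp["x1"] > imp["x2"]
  }, logical(1))
  expect_gte(sum(wins), 95)

  sole <- fit_rf(data.frame(x1 = rnorm(100)), rbinom(100, 1, 0.5),
                 n_trees = 50, seed = 1)
  imp <- gini_importance(sole)
  expect_length(imp, 1)
  expect_gte(imp[["x1"]], 0)
})

test_that("all-noise variables show no spurious dominant importance", {
  calm <- vapply(1:100, function(seed) {
    d <- with_seed(seed + 500, data.frame(matrix(rnorm(150 * 4), ncol = 4),
                                          label = rbinom(150, 1, 0.5)))
    fit <- fit_rf(d[, 1:4], d$label, n_trees = 50, seed = seed)
    imp <- gini_importance(fit)
    max(imp) <= 3 * stats::median(imp)
  }, logical(1))
  expect_gte(sum(calm), 90)
})

test_that("median importance reproduces the published ranking rule", {
  tbl <- reported_mdg()
  tables <- list(
    b = stats::setNames(tbl$G_brevicaudus, tbl$variable),
    u = stats::setNames(tbl$G_ussuriensis, tbl$variable),
    s = stats::setNames(tbl$G_saxatilis, tbl$variable))
  med <- median_importance(tables)
  expect_equal(med$median[med$variable == "tpi"], 76.25)
  expect_equal(med$median[med$variable == "slope"], 53.17)
  # every printed median matches the rule applied to the printed triplets
  m <- merge(med, tbl, by = "variable")
  expect_equal(m$median, m$median_printed)
  expect_equal(med$variable[1], "tpi")

  single <- median_importance(tables["b"])
  expect_equal(stats::setNames(single$median, single$variable),
               sort(tables$b, decreasing = TRUE))
  expect_error(median_importance(list(a = c(x = 1), b = c(y = 1))),
               "different variable sets")
})

test_that("response curves recover monotone truth and stay flat under null", {
  d <- with_seed(12, {
    x <- rnorm(300)
    data.frame(x = x, z = rnorm(300), label = as.integer(x > 0))
  })
  fit <- fit_rf(d[, c("x", "z")], d$label, n_trees = 300, seed = 1)
  rc <- response_curve(fit, d[, c("x", "z")], "x", n_grid = 30)
  expect_true(all(diff(rc$value) > 0))
  expect_true(all(diff(rc$probability) >= -0.01))  # monotone up to vote jitter
  expect_gt(rc$probability[30] - rc$probability[1], 0.5)

  rn <- response_curve(fit, d[, c("x", "z")], "z", n_grid = 30)
  expect_lt(diff(range(rn$probability)), 0.1)
  expect_error(response_curve(fit, d, "missing_var"), "not in data")
})

test_that("surface prediction and binarization honor thresholds and nodata", {
  sys <- list(
    tpi = mk_grid(matrix(rnorm(64), 8)),
    slope = mk_grid(matrix(runif(64, 0, 30), 8)))
  sys$tpi$values[1, 1] <- NA
  stack <- predictor_stack(sys)
  d <- with_seed(3, data.frame(tpi = rnorm(200), slope = runif(200, 0, 30)))
  y <- as.integer(d$tpi < 0)
  fit <- fit_rf(d, y, n_trees = 100, seed = 2)
  surf <- predict_surface(fit, stack)
  expect_true(is.na(surf$values[1, 1]))
  expect_true(all(surf$values >= 0 & surf$values <= 1, na.rm = TRUE))

  expect_true(all(binarize(surf, 0)$values == 1, na.rm = TRUE))
  expect_true(all(binarize(surf, 1 + 1e-9)$values == 0, na.rm = TRUE))
  thr <- 0.4
  bin <- binarize(surf, thr)
  expect_equal(sum(bin$values, na.rm = TRUE),
               sum(surf$values >= thr, na.rm = TRUE))
  expect_error(predict_surface(fit, predictor_stack(sys["tpi"])),
               "slope")
})

test_that("the SDM report satisfies its identities and threshold optimality", {
  d <- with_seed(33, {
    x1 <- rnorm(300); x2 <- rnorm(300)
    data.frame(x1 = x1, x2 = x2,
               label = rbinom(300, 1, plogis(1.5 * x1 - x2)))
  })
  rep <- fit_sdm(d, seed = 7, n_trees = 200, k = 5, tune = FALSE,
                 cv_trees = 100)
  expect_identical(rep$tss_train, rep$sens_train + rep$spec_train - 1)
  expect_identical(rep$tss_test, rep$sens_test + rep$spec_test - 1)
  expect_length(rep$cv$fold_auc, 5)
  expect_equal(rep$cv$mean, mean(rep$cv$fold_auc))

  tr <- rep$data$split == "train"
  scores <- rf_scores(rep$model, rep$data[tr, c("x1", "x2")])
  ref <- threshold_exhaustive(scores, rep$data$label[tr])
  expect_equal(rep$sens_train + rep$spec_train, ref$best_sum)
  expect_equal(rep$threshold, ref$threshold)
})
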