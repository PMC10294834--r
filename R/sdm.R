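covariate_names <- function(data) {
  setdiff(names(data), c("species", "x", "y", "label", "split", "fold"))
}

#' Stratified train/test split
#'
#' Adds a `split` column ("train"/"test") with a per-class random split:
#' `round(train_frac * n)` points of each label class go to training, so the
#' class balance is preserved within +-1 point. Reproducible by `seed`.
#'
#' @param data Labeled data frame (must contain `label` with both classes).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return `data` with a `split` column.
#' @export
split_train_test <- function(data, train_frac = 0.7, seed = 1L) {
  stopifnot(all(data$label %in% c(0, 1)))
  tab <- table(factor(data$label, levels = c(0, 1)))
  if (any(tab < 2)) stop("each class needs at least 2 points to split")
  split <- rep("test", nrow(data))
  with_seed(seed, {
    for (cl in c(0, 1)) {
      ix <- which(data$label == cl)
      n_tr <- round(train_frac * length(ix))
      split[sample(ix, n_tr)] <- "train"
    }
  })
  data$split <- split
  data
}

#' Assign stratified cross-validation folds
#'
#' @param labels 0/1 vector.
#' @param k Number of folds; every class must have at least `k` points.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per point.
#' @export
assign_folds <- function(labels, k = 10, seed = 1L) {
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < k))
    stop("class with ", min(tab), " points cannot be split into ", k, " folds")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(0, 1)) {
      ix <- which(labels == cl)
      fold[ix] <- sample(rep(seq_len(k), length.out = length(ix)))
    }
  })
  fold
}

# Candidate mtry ladder: floor(sqrt(p)) and its doublings/halvings within [1, p].
mtry_candidates <- function(p) {
  m0 <- max(1L, floor(sqrt(p)))
  up <- m0
  while (up[length(up)] * 2L <= p) up <- c(up, up[length(up)] * 2L)
  down <- m0
  while (down[length(down)] %/% 2L >= 1L) down <- c(down, down[length(down)] %/% 2L)
  sort(unique(c(up, down, 1L, p)))
}

#' Tune the number of split variables by out-of-bag error
#'
#' Evaluates a doubling/halving ladder of candidate `mtry` values around
#' `floor(sqrt(p))` and returns the candidate with the smallest out-of-bag
#' classification error (ties go to the smaller `mtry`).
#'
#' @param X Covariate data frame/matrix (training points).
#' @param y 0/1 labels.
#' @param n_trees Trees per candidate forest.
#' @param seed Integer seed.
#' @return List with `mtry`, and `oob` (named error per candidate).
#' @export
tune_mtry <- function(X, y, n_trees = 250, seed = 1L) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p == 1) return(list(mtry = 1L, oob = c(`1` = NA_real_)))
  cands <- mtry_candidates(p)
  oob <- vapply(cands, function(m) {
    fit <- with_seed(seed + m, randomForest::randomForest(
      x = X, y = factor(y, levels = c(0, 1)), ntree = n_trees, mtry = m))
    unname(fit$err.rate[n_trees, "OOB"])
  }, numeric(1))
  names(oob) <- cands
  list(mtry = cands[which.min(oob)], oob = oob)
}

#' Fit a random-forest presence/pseudo-absence classifier
#'
#' An ensemble of unpruned classification trees grown on bootstrap resamples
#' (with duplicates); the predicted presence probability of a point is the
#' fraction of trees voting presence. Deterministic given `seed`.
#'
#' @param X Covariate data frame (training points).
#' @param y 0/1 labels (both classes required).
#' @param mtry Variables tried per split (see [tune_mtry()]).
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed.
#' @return A `randomForest` fit with attributes `seed` and `covariates`.
#' @export
fit_rf <- function(X, y, mtry = NULL, n_trees = 1000, seed = 1L) {
  X <- as.data.frame(X)
  if (length(unique(y)) < 2) stop("training set has a single class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  fit <- with_seed(seed, randomForest::randomForest(
    x = X, y = factor(y, levels = c(0, 1)), ntree = n_trees, mtry = mtry,
    importance = FALSE))
  attr(fit, "seed") <- seed
  attr(fit, "covariates") <- names(X)
  fit
}

#' Predicted presence probability (tree-vote fraction)
#'
#' @param model A fitted [fit_rf()] model.
#' @param X New covariate data.
#' @return Numeric vector of presence probabilities in `[0, 1]`.
#' @export
rf_scores <- function(model, X) {
  unname(stats::predict(model, newdata = as.data.frame(X),
                        type = "prob")[, "1"])
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen presence outscores a randomly
#' chosen absence, with ties counted one half. Invariant under strictly
#' increasing transforms of the scores.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined with a single class")
  r <- rank(scores)                      # mid-ranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximizing sensitivity plus specificity
#'
#' Scans candidate thresholds — midpoints between consecutive sorted unique
#' scores, plus 0 and 1 — predicting presence where `score >= threshold`,
#' and returns the threshold with maximal sensitivity + specificity (ties go
#' to the smallest threshold). This is the binarization rule used for the
#' species habitat maps.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels 0/1 labels (both classes required).
#' @return List with `threshold`, `sens`, `spec`.
#' @export
select_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  if (!length(s1) || !length(s0)) stop("both classes required")
  u <- sort(unique(scores))
  cands <- sort(unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)))
  sens <- vapply(cands, function(t) mean(s1 >= t), numeric(1))
  spec <- vapply(cands, function(t) mean(s0 < t), numeric(1))
  best <- which.max(sens + spec)         # first index = smallest threshold
  list(threshold = cands[best], sens = sens[best], spec = spec[best])
}

#' True skill statistic
#'
#' `sensitivity + specificity - 1`: 1 is perfect, 0 random, negative worse
#' than random; unlike kappa it is insensitive to prevalence.
#'
#' @param sens,spec Values in `[0, 1]`.
#' @export
tss <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  sens + spec - 1
}

#' Stratified k-fold cross-validated AUC
#'
#' Partitions the training points into `k` stratified folds; for each fold,
#' re-tunes `mtry` on the remaining folds (no leakage), fits, and scores the
#' held-out fold.
#'
#' @param X Covariates (training points).
#' @param y 0/1 labels.
#' @param k Folds (default 10); every class needs >= k points.
#' @param seed Integer seed.
#' @param n_trees Trees per fold model.
#' @param tune Re-tune `mtry` per fold? Default `TRUE`.
#' @return List with `fold_auc` (length k), `mean`, `sd`.
#' @export
cross_validate <- function(X, y, k = 10, seed = 1L, n_trees = 500,
                           tune = TRUE) {
  X <- as.data.frame(X)
  fold <- assign_folds(y, k = k, seed = seed)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    m <- if (tune && ncol(X) > 1)
      tune_mtry(X[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                seed = seed + 100 * f)$mtry
    else max(1L, floor(sqrt(ncol(X))))
    fit <- fit_rf(X[tr, , drop = FALSE], y[tr], mtry = m, n_trees = n_trees,
                  seed = seed + f)
    roc_auc(rf_scores(fit, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  list(fold_auc = aucs, mean = mean(aucs), sd = stats::sd(aucs))
}

#' Mean decrease Gini importance
#'
#' @param model A fitted [fit_rf()] model.
#' @return Named numeric vector (>= 0), one entry per covariate.
#' @export
gini_importance <- function(model) {
  imp <- randomForest::importance(model, type = 2)
  stats::setNames(as.numeric(imp), rownames(imp))
}

#' Median importance across species models
#'
#' Ranks variables by the median of their mean-decrease-Gini importance
#' across the per-species models; the top three carry the response curves.
#'
#' @param tables Named list of per-species importance vectors (identical
#'   variable sets).
#' @return Data frame with per-species columns, `median`, `rank`, `top3`,
#'   sorted by descending median.
#' @export
median_importance <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  vars <- sort(names(tables[[1]]))
  for (tb in tables)
    if (!identical(sort(names(tb)), vars))
      stop("importance tables cover different variable sets")
  m <- sapply(tables, function(tb) tb[vars])
  if (is.null(dim(m))) m <- matrix(m, ncol = 1, dimnames = list(vars, names(tables)))
  med <- apply(m, 1, stats::median)
  out <- data.frame(variable = vars, m, median = med, check.names = FALSE)
  out <- out[order(-out$median, out$variable), ]
  out$rank <- seq_len(nrow(out))
  out$top3 <- out$rank <= 3
  rownames(out) <- NULL
  out
}

#' Partial-dependence response curve
#'
#' For each of `n_grid` values spanning the variable's observed range, sets
#' the variable to that value for every row of `data` and averages the
#' predicted presence probability — the model-averaged response shape.
#'
#' @param model A fitted [fit_rf()] model.
#' @param data Covariate data frame (typically the training points).
#' @param variable Covariate name.
#' @param n_grid Grid resolution (default 50).
#' @return Data frame `value`, `probability` of class `response_curve`.
#' @export
response_curve <- function(model, data, variable, n_grid = 50) {
  data <- as.data.frame(data)
  if (!variable %in% names(data)) stop("variable '", variable, "' not in data")
  rng <- range(data[[variable]])
  grid <- if (diff(rng) == 0) rng[1] else seq(rng[1], rng[2], length.out = n_grid)
  prob <- vapply(grid, function(v) {
    d <- data
    d[[variable]] <- v
    mean(rf_scores(model, d))
  }, numeric(1))
  structure(data.frame(value = grid, probability = prob),
            variable = variable, class = c("response_curve", "data.frame"))
}

#' Predict a suitability surface over a stack
#'
#' @param model A fitted [fit_rf()] model.
#' @param stack A [predictor_stack()] containing every model covariate.
#' @return A probability [grid_layer()]; nodata propagates.
#' @export
predict_surface <- function(model, stack) {
  vars <- attr(model, "covariates")
  if (is.null(vars)) vars <- rownames(model$importance)
  missing <- setdiff(vars, stack$names)
  if (length(missing))
    stop("stack is missing model variable(s): ", paste(missing, collapse = ", "))
  s <- stack$spec
  newdata <- as.data.frame(lapply(stack$layers[vars], function(g) as.vector(g$values)))
  ok <- stats::complete.cases(newdata)
  out <- rep(NA_real_, nrow(newdata))
  if (any(ok)) out[ok] <- rf_scores(model, newdata[ok, , drop = FALSE])
  grid_layer(matrix(out, s$n_rows, s$n_cols), s)
}

#' Binarize a suitability surface
#'
#' @param surface Probability [grid_layer()].
#' @param threshold Cells with `probability >= threshold` become 1, else 0;
#'   `NA` propagates.
#' @return Binary [grid_layer()].
#' @export
binarize <- function(surface, threshold) {
  v <- ifelse(surface$values >= threshold, 1, 0)
  grid_layer(matrix(v, nrow(surface$values)), surface$spec)
}

#' Fit and evaluate one species distribution model
#'
#' The per-species workhorse: stratified 70/30 split, out-of-bag `mtry`
#' tuning, random-forest fit, AUC on both splits, threshold selected on the
#' TRAINING scores by maximizing sensitivity + specificity (then applied
#' unchanged to the test split, avoiding leakage), TSS on both splits,
#' stratified k-fold cross-validated AUC, and mean-decrease-Gini importance.
#'
#' @param data Labeled data frame: `label` plus covariate columns (columns
#'   `species`, `x`, `y` are carried but not modelled).
#' @param seed Integer seed governing split, tuning, fit and folds.
#' @param n_trees Trees in the final model (default 1000).
#' @param train_frac Training fraction (default 0.7).
#' @param k Cross-validation folds (default 10); skipped if `k < 2`.
#' @param tune Tune `mtry` (default `TRUE`); otherwise `floor(sqrt(p))`.
#' @param cv_trees,tune_trees Trees used during cross-validation and tuning.
#' @return An `sdm_report` list; see Details.
#' @details The report fields: `model`, `mtry`, `n_trees`, `seed`,
#'   `auc_train`, `auc_test`, `threshold`, `sens_train`, `spec_train`,
#'   `sens_test`, `spec_test`, `tss_train`, `tss_test`, `cv` (fold AUCs,
#'   mean, sd), `importance`, `data` (with split tags).
#' @export
fit_sdm <- function(data, seed = 1L, n_trees = 1000, train_frac = 0.7,
                    k = 10, tune = TRUE, cv_trees = 500, tune_trees = 250) {
  vars <- covariate_names(data)
  if (!length(vars)) stop("no covariate columns in data")
  data <- split_train_test(data, train_frac = train_frac, seed = seed)
  tr <- data$split == "train"
  Xtr <- data[tr, vars, drop = FALSE]
  ytr <- data$label[tr]
  mtry <- if (tune && length(vars) > 1)
    tune_mtry(Xtr, ytr, n_trees = tune_trees, seed = seed)$mtry
  else max(1L, floor(sqrt(length(vars))))
  model <- fit_rf(Xtr, ytr, mtry = mtry, n_trees = n_trees, seed = seed)
  str_scores <- rf_scores(model, Xtr)
  ste_scores <- rf_scores(model, data[!tr, vars, drop = FALSE])
  yte <- data$label[!tr]
  thr <- select_threshold(str_scores, ytr)
  sens_te <- mean(ste_scores[yte == 1] >= thr$threshold)
  spec_te <- mean(ste_scores[yte == 0] < thr$threshold)
  cv <- if (k >= 2)
    cross_validate(Xtr, ytr, k = k, seed = seed, n_trees = cv_trees,
                   tune = tune)
  else NULL
  structure(list(
    model = model, mtry = mtry, n_trees = n_trees, seed = seed,
    auc_train = roc_auc(str_scores, ytr),
    auc_test = roc_auc(ste_scores, yte),
    threshold = thr$threshold,
    sens_train = thr$sens, spec_train = thr$spec,
    sens_test = sens_te, spec_test = spec_te,
    tss_train = tss(thr$sens, thr$spec),
    tss_test = tss(sens_te, spec_te),
    cv = cv,
    importance = gini_importance(model),
    data = data
  ), class = "sdm_report")
}

#' @export
print.sdm_report <- function(x, ...) {
  cat(sprintf("<sdm_report> mtry %d, %d trees, seed %d\n",
              x$mtry, x$n_trees, x$seed))
  cat(sprintf("  AUC train %.3f / test %.3f; threshold %.3f; TSS train %.3f / test %.3f\n",
              x$auc_train, x$auc_test, x$threshold, x$tss_train, x$tss_test))
  if (!is.null(x$cv))
    cat(sprintf("  CV AUC %.3f (SD %.3f, %d folds)\n",
                x$cv$mean, x$cv$sd, length(x$cv$fold_auc)))
  top <- sort(x$importance, decreasing = TRUE)
  cat("  importance:", paste(sprintf("%s %.1f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an SDM report's metrics to JSON
#'
#' @param report An `sdm_report`.
#' @param path Output JSON path.
#' @export
write_sdm_report <- function(report, path) {
  jsonlite::write_json(list(
    mtry = report$mtry, n_trees = report$n_trees, seed = report$seed,
    auc_train = report$auc_train, auc_test = report$auc_test,
    threshold = report$threshold,
    sens_train = report$sens_train, spec_train = report$spec_train,
    sens_test = report$sens_test, spec_test = report$spec_test,
    tss_train = report$tss_train, tss_test = report$tss_test,
    cv_auc_mean = if (is.null(report$cv)) NULL else report$cv$mean,
    cv_auc_sd = if (is.null(report$cv)) NULL else report$cv$sd,
    cv_auc_folds = if (is.null(report$cv)) NULL else report$cv$fold_auc,
    importance = as.list(report$importance)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
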