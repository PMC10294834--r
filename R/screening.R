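#' Kendall's tau-b rank correlation
#'
#' Knight's O(n log n) algorithm (compiled), handling ties as tau-b.
#' Equivalent to `cor(x, y, method = "kendall")` but fast enough for the
#' repeated screening runs on model-sized datasets.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Tau-b in `[-1, 1]`; `NA` if either vector is constant.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  .kendall_tau_cpp(as.numeric(x[ok]), as.numeric(y[ok]))
}

#' Pairwise correlation triplets
#'
#' For every unordered pair of columns, the Pearson, Spearman and Kendall
#' coefficients. Collinearity screening flags a pair when ANY of the three
#' exceeds the threshold in absolute value. Constant columns are flagged and
#' get `NA` coefficients (they correlate with nothing).
#'
#' @param X Data frame or matrix of candidate predictor values at the model
#'   points.
#' @return Data frame with columns `var1`, `var2`, `pearson`, `spearman`,
#'   `kendall`, `max_abs`.
#' @export
pairwise_correlations <- function(X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 variables")
  nms <- names(X)
  const <- vapply(X, function(v) stats::var(v, na.rm = TRUE) == 0, logical(1))
  if (any(const))
    warning("constant variable(s): ", paste(nms[const], collapse = ", "))
  pairs <- utils::combn(p, 2)
  res <- data.frame(var1 = nms[pairs[1, ]], var2 = nms[pairs[2, ]],
                    pearson = NA_real_, spearman = NA_real_,
                    kendall = NA_real_)
  cp <- suppressWarnings(stats::cor(X, method = "pearson"))
  cs <- suppressWarnings(stats::cor(X, method = "spearman"))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (const[i] || const[j]) next
    res$pearson[k] <- cp[i, j]
    res$spearman[k] <- cs[i, j]
    res$kendall[k] <- kendall_tau(X[[i]], X[[j]])
  }
  res$max_abs <- pmax(abs(res$pearson), abs(res$spearman), abs(res$kendall))
  res
}

#' Percent deviance explained by one predictor
#'
#' Fits a univariate binomial regression of the 0/1 label on `x` — a smooth
#' (thin-plate spline via `mgcv::gam`) when it converges, otherwise a linear
#' GLM — and returns `100 * (null - residual) / null` deviance. The smooth
#' matters because several responses here are non-monotone (temperature
#' window, slope optimum). Perfect separation returns a value capped at 100
#' with a warning; a constant predictor returns 0.
#'
#' @param x Predictor values.
#' @param labels 0/1 outcome (both classes present).
#' @param smooth Attempt the spline fit (default); `FALSE` forces the
#'   linear GLM.
#' @return Percent deviance explained.
#' @export
univariate_deviance <- function(x, labels, smooth = TRUE) {
  stopifnot(length(x) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (stats::var(x) == 0) return(0)
  fit <- if (!smooth) NULL else tryCatch({
    g <- mgcv::gam(labels ~ s(x, k = 10), family = stats::binomial())
    if (!g$converged) stop("gam did not converge")
    g
  }, error = function(e) NULL)
  if (is.null(fit))
    fit <- suppressWarnings(stats::glm(labels ~ x, family = stats::binomial()))
  pd <- 100 * (fit$null.deviance - fit$deviance) / fit$null.deviance
  if (pd > 100 - 1e-8 || fit$deviance < 1e-6) {
    warning("(near-)perfect separation; deviance explained capped at 100")
    pd <- min(pd, 100)
  }
  pd
}

#' Collinearity screening of candidate predictors
#'
#' Iteratively removes variables until no retained pair has an absolute
#' Pearson, Spearman or Kendall correlation above `threshold`. At each step
#' the pair with the largest max-|r| is processed first and the member with
#' the LOWER univariate percent deviance explained is dropped (ties drop the
#' alphabetically later name), so the screened set keeps the predictors that
#' carry more signal about the labels.
#'
#' @param X Data frame of candidate predictors at the model points.
#' @param labels 0/1 labels aligned with `X`'s rows.
#' @param threshold Correlation threshold (default 0.75).
#' @param deviance_for `"all"` computes deviance explained for every
#'   variable (full report); `"flagged"` only for variables involved in an
#'   above-threshold pair — the only deviances the drop decisions use —
#'   leaving the rest `NA` (cheaper on repeated simulation runs).
#' @return A `screening_report`: list with `correlations` (the triplet
#'   table), `deviance` (named percent per variable), `retained` (ordered
#'   names), `dropped` (data frame `variable`, `because_of`).
#' @export
screen_collinear <- function(X, labels, threshold = 0.75,
                             deviance_for = c("all", "flagged")) {
  deviance_for <- match.arg(deviance_for)
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need at least 2 variables to screen")
  corr <- pairwise_correlations(X)
  flagged <- !is.na(corr$max_abs) & corr$max_abs > threshold
  need <- if (deviance_for == "all") names(X) else
    intersect(names(X), unique(c(corr$var1[flagged], corr$var2[flagged])))
  dev <- stats::setNames(rep(NA_real_, ncol(X)), names(X))
  dev[need] <- vapply(need, function(nm) {
    if (stats::var(X[[nm]]) == 0) 0 else univariate_deviance(X[[nm]], labels)
  }, numeric(1))
  active <- names(X)
  dropped <- data.frame(variable = character(), because_of = character())
  repeat {
    live <- corr[corr$var1 %in% active & corr$var2 %in% active &
                   !is.na(corr$max_abs) & corr$max_abs > threshold, ]
    if (nrow(live) == 0) break
    live <- live[order(-live$max_abs, live$var1, live$var2), ]
    a <- live$var1[1]; b <- live$var2[1]
    loser <- if (dev[a] < dev[b]) a
             else if (dev[b] < dev[a]) b
             else max(a, b)                 # tie: drop alphabetically later
    winner <- if (loser == a) b else a
    dropped <- rbind(dropped,
                     data.frame(variable = loser, because_of = winner))
    active <- setdiff(active, loser)
  }
  structure(list(correlations = corr, deviance = dev,
                 retained = active, dropped = dropped,
                 threshold = threshold),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report> threshold", x$threshold, "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped))
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  dropped %s (collinear with %s; %.2f%% vs %.2f%% deviance)\n",
                  x$dropped$variable[i], x$dropped$because_of[i],
                  x$deviance[x$dropped$variable[i]],
                  x$deviance[x$dropped$because_of[i]]))
  invisible(x)
}

#' Serialize a screening report
#'
#' @param report A `screening_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @export
write_screening_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(
      list(threshold = report$threshold, retained = report$retained,
           dropped = report$dropped, deviance = as.list(report$deviance)),
      json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(report$correlations, csv_path, row.names = FALSE)
  invisible(report)
}
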