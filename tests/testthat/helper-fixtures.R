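# Shared fixture builders: everything is generated in code at test time.

# A grid from a matrix with unit default geometry.
mk_grid <- function(m, cell = 1, origin_x = 0, origin_y = nrow(m) * cell,
                    nodata = -9999) {
  grid_layer(as.matrix(m), grid_spec(nrow(m), ncol(m), cell_size = cell,
                                     origin_x = origin_x, origin_y = origin_y,
                                     nodata = nodata))
}

# Small labelled dataset where the label depends on the first covariate.
mk_separable <- function(n = 200, seed = 1) {
  with_seed(seed, {
    x1 <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
    data.frame(x1 = x1, x2 = rnorm(n), label = rep(c(0L, 1L), each = n / 2))
  })
}

# with_seed is internal; re-export for test code.
with_seed <- sdmrisk:::with_seed

# Brute-force Kendall tau-b by O(n^2) pair counting (ties handled).
kendall_pairs <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# Brute-force AUC by pairwise concordance counting.
auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# Exhaustive threshold search over all candidate cuts.
threshold_exhaustive <- function(scores, labels) {
  u <- sort(unique(scores))
  cands <- sort(unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)))
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  sums <- vapply(cands, function(t) mean(s1 >= t) + mean(s0 < t), numeric(1))
  list(best_sum = max(sums), threshold = cands[which.max(sums)])
}
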