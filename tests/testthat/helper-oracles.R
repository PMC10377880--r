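# Independent brute-force oracles used across the suite.  These deliberately
# share no code with the production paths they check.

# Box counting by explicit cell-tuple construction: paste each point's
# per-axis cell indices into a string key and count distinct keys.
oracle_count_boxes <- function(pts, r) {
  idx <- pmin(floor(pts * r), r - 1)
  length(unique(apply(idx, 1, paste, collapse = ",")))
}

# 4D cloud as the literal union of per-sample 3D clouds.
oracle_cloud_4d <- function(mask, ncoords, start, width) {
  rows <- NULL
  for (t in seq(start, start + width - 1)) {
    active <- which(mask[, t])
    if (length(active))
      rows <- rbind(rows, cbind(ncoords[active, , drop = FALSE],
                                (t - start) / width))
  }
  if (is.null(rows)) rows <- matrix(numeric(0), ncol = 4)
  unique(rows)
}

# Exact two-sided Mann-Whitney p by enumeration of all label arrangements
# (no ties assumed; small n only).
oracle_mw_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  combos <- utils::combn(n, n1)
  u_of <- function(ix) {
    rk <- rank(pooled)
    sum(rk[ix]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  u_null <- apply(combos, 2, u_of)
  n2 <- n - n1
  dev_obs <- abs(u_obs - n1 * n2 / 2)
  mean(abs(u_null - n1 * n2 / 2) >= dev_obs - 1e-9)
}

# Classical no-ties Spearman formula.
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Direct-formula 2x2 chi-squared (no correction).
oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Exact dyadic box counts of the true middle-thirds Cantor set: enumerate
# its level-`level` cover intervals and mark every grid cell they touch.
cantor_dyadic_counts <- function(resolutions, level = 12) {
  lefts <- 0
  for (i in seq_len(level))
    lefts <- as.vector(outer(lefts, c(0, 2) * 3^-i, "+"))
  len <- 3^-level
  vapply(resolutions, function(r) {
    lo <- floor(lefts * r)
    hi <- floor(pmin(lefts + len, 1 - 1e-15) * r)
    length(unique(c(lo, hi)))
  }, numeric(1))
}

# Least-squares slope of log(counts) on log(r); the oracle-side regression.
loglog_slope <- function(r, counts) {
  x <- log(r); y <- log(counts)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Tiny epoch builders ------------------------------------------------------

epoch_from_values <- function(values, fs = length(values[1, ]),
                              coords = NULL, ...) {
  values <- rbind(values)
  if (is.null(coords))
    coords <- cbind(seq_len(nrow(values)), 0, 0)
  source_epoch(values, coords, fs = fs, ...)
}

random_cloud <- function(n, dim, seed) {
  withr::with_seed(seed, matrix(runif(n * dim), ncol = dim))
}
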