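#' Mann-Whitney U test for two independent samples
#'
#' Rank-sum comparison with midrank tie handling.  The p-value is two-sided:
#' exact (by enumeration of the null U distribution) when `n1 * n2 <= 400`
#' and the pooled sample has no ties, otherwise the tie-corrected normal
#' approximation without continuity correction.  The reported `u` is the
#' larger of the two orientations (so `u >= n1 * n2 / 2`), with `direction`
#' indicating which sample ranks higher; `u_x` is the U of the first sample
#' for identities such as AUC = U / (n1 n2).
#'
#' @param x,y numeric samples (non-empty).
#' @return a `group_comparison`: `u`, `u_x`, `p_value`, `n1`, `n2`,
#'   `direction` (`"x"`, `"y"` or `"tie"`), `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 9, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) == 0L || length(y) == 0L)
    stop_fd4d("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  ux <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  uy <- n1 * n2 - ux
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n1 * n2 <= 400) {
    u_min <- min(ux, uy)
    p <- min(1, 2 * pwilcox(u_min, n1, n2))
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- (ux - n1 * n2 / 2) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(u = max(ux, uy), u_x = ux, p_value = p, n1 = n1, n2 = n2,
                 direction = if (ux > uy) "x" else if (uy > ux) "y" else "tie",
                 method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U = %g (n1 = %d, n2 = %d, max %d), p = %.4g [%s]; %s\n",
              x$u, x$n1, x$n2, x$n1 * x$n2, x$p_value, x$method,
              switch(x$direction, x = "first sample ranks higher",
                     y = "second sample ranks higher", tie = "no rank difference")))
  invisible(x)
}

#' ROC area under the curve by the rank method
#'
#' Probability that a randomly chosen positive-class score exceeds a
#' randomly chosen negative-class score, with ties credited 0.5; identical to
#' `U_positive / (n_pos * n_neg)`.  Higher scores are taken to indicate the
#' positive class.
#'
#' @param scores numeric classifier scores (e.g. per-subject mean 4DFD).
#' @param labels class labels, two distinct values.
#' @param positive the label of the positive class; defaults to the first
#'   label in sort order.
#' @return the AUC (scalar in `[0, 1]`).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L)
    stop_fd4d("labels must contain exactly 2 classes (got %d)", length(lv))
  positive <- positive %||% lv[1]
  if (!positive %in% lv) stop_fd4d("positive class '%s' not in labels", positive)
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  rk <- rank(scores)
  u_pos <- sum(rk[pos]) - n1 * (n1 + 1) / 2
  u_pos / (n1 * n2)
}

#' ROC curve points
#'
#' False/true positive rates across all score thresholds, for export and
#' plotting.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  positive <- positive %||% lv[1]
  pos <- labels == positive
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)))
}

#' Spearman correlations with Bonferroni correction
#'
#' Rank correlation between a target column (default the subject-level mean
#' 4DFD) and each clinical score, on pairwise-complete rows.  Raw p-values
#' are multiplied by the number of simultaneous comparisons (capped at 1).
#' A pair with fewer than 4 complete rows or a constant column is reported
#' as missing with a reason rather than dropped silently.
#'
#' @param table data.frame with one row per subject.
#' @param score_names character vector of score columns to test.
#' @param target name of the target column (default `"mean_fd"`).
#' @return data.frame with `score`, `n`, `rho`, `p_raw`, `p_adj`,
#'   `significant`, `note`; the Bonferroni multiplier is attached as
#'   attribute `"multiplier"`.
#' @export
spearman_bonferroni <- function(table, score_names, target = "mean_fd") {
  stopifnot(is.data.frame(table), target %in% names(table))
  missing_cols <- setdiff(score_names, names(table))
  if (length(missing_cols))
    stop_fd4d("score columns not in table: %s", paste(missing_cols, collapse = ", "))
  m <- length(score_names)
  res <- lapply(score_names, function(s) {
    ok <- complete.cases(table[[target]], table[[s]])
    xs <- table[[target]][ok]; ys <- table[[s]][ok]
    if (sum(ok) < 4L)
      return(data.frame(score = s, n = sum(ok), rho = NA_real_, p_raw = NA_real_,
                        p_adj = NA_real_, significant = NA,
                        note = "fewer than 4 complete pairs"))
    if (length(unique(xs)) < 2L || length(unique(ys)) < 2L)
      return(data.frame(score = s, n = sum(ok), rho = NA_real_, p_raw = NA_real_,
                        p_adj = NA_real_, significant = NA,
                        note = "constant column: rho undefined"))
    ct <- suppressWarnings(
      stats::cor.test(xs, ys, method = "spearman", exact = NULL))
    p_adj <- min(1, ct$p.value * m)
    data.frame(score = s, n = sum(ok), rho = unname(ct$estimate),
               p_raw = ct$p.value, p_adj = p_adj,
               significant = p_adj < 0.05, note = "")
  })
  out <- do.call(rbind, res)
  attr(out, "multiplier") <- m
  out
}

#' First principal component of the clinical scores
#'
#' PCA on z-scored score columns (the instruments have incomparable scales),
#' complete cases only.  Returns the fraction of variance explained by the
#' leading component and the per-subject PC1 scores for downstream
#' correlation analysis.
#'
#' @inheritParams spearman_bonferroni
#' @param id_col column holding subject identifiers (default `"subject_id"`).
#' @return list with `explained` (PC1 variance fraction), `explained_all`
#'   (all components), `scores` (named PC1 scores), `loadings`, `n`.
#' @export
pca_first_component <- function(table, score_names, id_col = "subject_id") {
  stopifnot(is.data.frame(table), length(score_names) >= 2L)
  x <- table[, score_names, drop = FALSE]
  ok <- complete.cases(x)
  if (sum(ok) < 3L) stop_fd4d("need at least 3 complete subjects for PCA")
  x <- as.matrix(x[ok, , drop = FALSE])
  if (any(apply(x, 2, sd) == 0))
    stop_fd4d("constant score column: cannot z-score for PCA")
  pr <- prcomp(x, center = TRUE, scale. = TRUE)
  frac <- pr$sdev^2 / sum(pr$sdev^2)
  ids <- if (id_col %in% names(table)) table[[id_col]][ok] else which(ok)
  list(explained = frac[1], explained_all = frac,
       scores = setNames(pr$x[, 1], ids), loadings = pr$rotation[, 1],
       n = sum(ok))
}

#' Compare the per-second FD time courses of two groups
#'
#' For each window (second), averages the FD values of the subjects within
#' each group, producing two equal-length curves of per-second group means,
#' then compares the curves with [mann_whitney()].  Complete separation of
#' the curves yields the structural ceiling `U = T^2` (14,400 for 120-s
#' epochs).
#'
#' @param series_a,series_b each a list of `fd_series` (or a numeric matrix,
#'   windows in rows, subjects in columns) for one group.
#' @return a `group_comparison` (see [mann_whitney()]).
#' @export
per_second_comparison <- function(series_a, series_b) {
  as_mat <- function(s) {
    if (is.matrix(s)) return(s)
    stopifnot(is.list(s), length(s) >= 1L)
    vapply(s, function(f) {
      if (inherits(f, "fd_series")) f$values else as.numeric(f)
    }, numeric(length(if (inherits(s[[1]], "fd_series")) s[[1]]$values else s[[1]])))
  }
  ma <- as_mat(series_a); mb <- as_mat(series_b)
  if (nrow(ma) != nrow(mb))
    stop_fd4d("groups have different series lengths (%d vs %d)",
              nrow(ma), nrow(mb))
  mann_whitney(rowMeans(ma), rowMeans(mb))
}

#' Chi-squared test of a 2x2 contingency table
#'
#' Direct-formula Pearson chi-squared with 1 degree of freedom; Yates
#' continuity correction is off by default (matching common neurophysiology
#' reporting), available via `correct = TRUE`.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df`, `expected`.
#' @export
chisq_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop_fd4d("tab must be 2x2")
  if (any(tab < 0)) stop_fd4d("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_fd4d("degenerate table: a margin is all zero")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  adj <- if (correct) pmin(abs(tab - expected), 0.5) else 0
  stat <- sum((abs(tab - expected) - adj)^2 / expected)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, expected = expected)
}

#' Demographic comparability tests for a two-group cohort
#'
#' Chi-squared test (sex by group) and Mann-Whitney U tests (age, education)
#' on a subject table, mirroring the usual matched-cohort report.
#'
#' @param table data.frame with columns `group` plus any of `sex`, `age`,
#'   `education`.
#' @param correct continuity correction for the sex chi-squared test.
#' @return named list of test results (only for the columns present).
#' @export
demographics_tests <- function(table, correct = FALSE) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  g <- as.character(table$group)
  lv <- sort(unique(g))
  if (length(lv) != 2L) stop_fd4d("need exactly 2 groups")
  out <- list()
  if ("sex" %in% names(table))
    out$sex <- chisq_2x2(base::table(as.character(table$sex), g), correct = correct)
  for (v in intersect(c("age", "education"), names(table)))
    out[[v]] <- mann_whitney(table[[v]][g == lv[1]], table[[v]][g == lv[2]])
  out
}
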