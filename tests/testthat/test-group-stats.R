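test_that("mann_whitney matches exact enumeration on small samples", {
  cmp <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$u, 9)        # max-oriented
  expect_equal(cmp$u_x, 0)
  expect_equal(cmp$p_value, 0.1)  # 2/20 arrangements are as extreme
  expect_equal(cmp$direction, "y")
  expect_equal(cmp$p_value, oracle_mw_exact(c(1, 2, 3), c(4, 5, 6)))

  for (case in 1:10) {
    x <- withr::with_seed(100 + case, rnorm(4))
    y <- withr::with_seed(200 + case, rnorm(5))
    cmp <- mann_whitney(x, y)
    expect_equal(cmp$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-12, info = paste("case", case))
  }
})

test_that("mann_whitney tie handling and orientation", {
  x <- c(1, 2, 3, 4)
  cmp <- mann_whitney(x, x)  # identical samples: U = n^2/2 under midranks
  expect_equal(cmp$u, 8)
  expect_equal(cmp$direction, "tie")
  expect_equal(cmp$p_value, 1)

  # perfectly separated 27 vs 15 -> ceiling U = 405
  cmp <- mann_whitney(seq_len(27) + 100, seq_len(15))
  expect_equal(cmp$u, 405)
  expect_equal(cmp$u, cmp$n1 * cmp$n2)
  expect_equal(cmp$direction, "x")
  expect_lt(cmp$p_value, 0.001)

  # with ties, the tie-corrected normal approximation must match stats::
  x <- withr::with_seed(7, sample(1:5, 30, replace = TRUE))
  y <- withr::with_seed(8, sample(2:6, 25, replace = TRUE))
  cmp <- mann_whitney(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(cmp$u_x, unname(ref$statistic))

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("ROC AUC equals U/(n1 n2) and handles degenerate scores", {
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c("a", "a", "a", "b", "b"),
                       positive = "a"), 1)
  expect_equal(roc_auc(rep(3, 6), rep(c("a", "b"), 3), positive = "a"), 0.5)
  expect_error(roc_auc(1:3, c("a", "a", "a")), "2 classes")

  for (case in 1:100) {
    n1 <- withr::with_seed(300 + case, sample(3:20, 1))
    n2 <- withr::with_seed(400 + case, sample(3:20, 1))
    scores <- withr::with_seed(500 + case,
                               round(rnorm(n1 + n2), 1))  # induce ties
    labels <- rep(c("pos", "neg"), c(n1, n2))
    auc <- roc_auc(scores, labels, positive = "pos")
    cmp <- mann_whitney(scores[labels == "pos"], scores[labels == "neg"])
    expect_equal(auc, cmp$u_x / (n1 * n2), info = paste("case", case))
  }
})

test_that("roc_curve starts at (0,0), ends at (1,1) and is monotone", {
  scores <- withr::with_seed(9, rnorm(30))
  labels <- rep(c("a", "b"), 15)
  rc <- roc_curve(scores, labels, positive = "a")
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("spearman_bonferroni: rho, adjustment and degenerate columns", {
  tab <- data.frame(subject_id = 1:8, mean_fd = c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8))
  tab$mono <- exp(tab$mean_fd)          # monotone transform -> rho 1
  tab$anti <- -tab$mean_fd              # rho -1
  tab$flat <- 7                         # constant -> undefined
  res <- spearman_bonferroni(tab, c("mono", "anti", "flat"))
  expect_equal(res$rho[res$score == "mono"], 1)
  expect_equal(res$rho[res$score == "anti"], -1)
  expect_true(is.na(res$rho[res$score == "flat"]))
  expect_match(res$note[res$score == "flat"], "constant")
  expect_equal(attr(res, "multiplier"), 3)

  # no-ties direct formula oracle at n = 5
  x <- c(2.2, 1.1, 5.5, 3.3, 4.4)
  y <- c(1.0, 0.5, 2.0, 9.0, 3.0)
  tab5 <- data.frame(subject_id = 1:5, mean_fd = x, s = y)
  res5 <- spearman_bonferroni(tab5, "s")
  expect_equal(res5$rho, oracle_spearman(x, y))

  # Bonferroni: adjusted >= raw, capped at 1
  tabr <- data.frame(subject_id = 1:12,
                     mean_fd = withr::with_seed(10, rnorm(12)))
  for (k in 1:5) tabr[[paste0("v", k)]] <- withr::with_seed(20 + k, rnorm(12))
  resr <- spearman_bonferroni(tabr, paste0("v", 1:5))
  expect_true(all(resr$p_adj >= resr$p_raw))
  expect_true(all(resr$p_adj <= 1))

  expect_error(spearman_bonferroni(tab, "absent"), "not in table")
  short <- data.frame(subject_id = 1:3, mean_fd = 1:3, s = c(1, NA, 2))
  expect_match(spearman_bonferroni(short, "s")$note, "fewer than 4")
})

test_that("pca_first_component explains variance as the factor model predicts", {
  # two perfectly correlated scores -> PC1 explains 100%
  tab <- data.frame(subject_id = 1:10, a = 1:10, b = 2 * (1:10) + 5)
  res <- pca_first_component(tab, c("a", "b"))
  expect_equal(res$explained, 1)
  expect_equal(sum(res$explained_all), 1)

  # two independent equal-variance scores, large n -> fraction near 0.5
  tab2 <- data.frame(subject_id = 1:2000,
                     a = withr::with_seed(31, rnorm(2000)),
                     b = withr::with_seed(32, rnorm(2000)))
  expect_lt(abs(pca_first_component(tab2, c("a", "b"))$explained - 0.5), 0.05)

  # one-factor model with loading l on p standardized variables:
  # PC1 fraction -> (1 + (p - 1) l^2) / p
  l <- 0.95; p <- 4; n <- 1500
  f <- withr::with_seed(33, rnorm(n))
  tab3 <- data.frame(subject_id = seq_len(n))
  for (k in seq_len(p))
    tab3[[paste0("s", k)]] <- l * f +
      sqrt(1 - l^2) * withr::with_seed(40 + k, rnorm(n))
  frac <- pca_first_component(tab3, paste0("s", 1:p))$explained
  expect_lt(abs(frac - (1 + (p - 1) * l^2) / p), 0.05)

  expect_error(pca_first_component(tab[1:2, ], c("a", "b")), "at least 3")
  tab$c <- 1
  expect_error(pca_first_component(tab, c("a", "c")), "constant")
})

test_that("per_second_comparison compares per-window group mean curves", {
  # fully separated curves of length T -> ceiling U = T^2
  t_len <- 120
  a <- lapply(1:5, function(i) 2 + withr::with_seed(50 + i, runif(t_len, 0, 0.1)))
  b <- lapply(1:4, function(i) 1 + withr::with_seed(60 + i, runif(t_len, 0, 0.1)))
  cmp <- per_second_comparison(a, b)
  expect_equal(cmp$u, t_len^2)

  # identical group curves -> U = T^2/2
  cmp2 <- per_second_comparison(a, a)
  expect_equal(cmp2$u, t_len^2 / 2)

  # T = 5 hand-built curves (tie-free means) vs exhaustive rank computation
  ma <- cbind(c(1, 5, 2, 8, 3), c(2, 6, 3, 9, 4))
  mb <- cbind(c(4, 1.2, 7, 2.2, 6), c(5, 1.6, 8, 1.4, 7))
  cmp3 <- per_second_comparison(ma, mb)
  ref <- mann_whitney(rowMeans(ma), rowMeans(mb))
  expect_equal(cmp3$u, ref$u)
  expect_equal(cmp3$p_value, oracle_mw_exact(rowMeans(ma), rowMeans(mb)))

  expect_error(per_second_comparison(ma, mb[1:4, ]), "different series lengths")
})

test_that("chi-squared 2x2 matches the direct formula", {
  expect_equal(chisq_2x2(rbind(c(5, 5), c(8, 8)))$statistic, 0)

  tab <- rbind(c(12, 15), c(7, 8))
  res <- chisq_2x2(tab)
  expect_equal(res$statistic, oracle_chisq_2x2(tab))
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  # Yates correction flag against stats::
  refc <- chisq.test(rbind(c(12, 5), c(7, 11)), correct = TRUE)
  resc <- chisq_2x2(rbind(c(12, 5), c(7, 11)), correct = TRUE)
  expect_equal(resc$statistic, unname(refc$statistic))

  expect_error(chisq_2x2(rbind(c(0, 0), c(3, 4))), "margin")
  expect_error(chisq_2x2(matrix(1, 3, 2)), "2x2")
})

test_that("demographics_tests assembles the matched-cohort battery", {
  tab <- data.frame(
    group = rep(c("groupA", "groupB"), c(27, 15)),
    sex = withr::with_seed(70, sample(c("F", "M"), 42, replace = TRUE)),
    age = withr::with_seed(71, rnorm(42, 68, 6)),
    education = withr::with_seed(72, rnorm(42, 12, 3)))
  res <- demographics_tests(tab)
  expect_named(res, c("sex", "age", "education"))
  ref <- chisq.test(table(tab$sex, tab$group), correct = FALSE)
  expect_equal(res$sex$statistic, unname(ref$statistic))
  expect_equal(res$age$u_x,
               unname(suppressWarnings(
                 wilcox.test(tab$age[tab$group == "groupA"],
                             tab$age[tab$group == "groupB"]))$statistic))
})
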