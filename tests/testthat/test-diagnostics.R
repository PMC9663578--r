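test_that("AUC equals the tie-corrected pair statistic on tie-rich data", {
  # perfectly separated toy
  s <- labeled_scores(c(10, 9, 8, 3, 2, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(roc_auc(s)$auc, 1.0)

  # hand-computed small case with one cross-class tie: pairs (3x3) = 9,
  # pos {5, 4, 2} vs neg {4, 1, 0}: wins 7, ties 1 -> (7 + 0.5) / 9
  tied <- labeled_scores(c(5, 4, 2, 4, 1, 0), rep(c(TRUE, FALSE), each = 3))
  expect_equal(roc_auc(tied)$auc, 7.5 / 9)

  # duality holds on random heavily tied inputs (asserted inside roc_auc,
  # and cross-checked against pROC's trapezoidal AUC)
  withr::with_seed(41, {
    for (i in 1:30) {
      n <- sample(6:25, 1)
      vals <- sample(0:6, n, replace = TRUE)           # many ties
      labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(labs)) < 2) next
      r <- roc_auc(labeled_scores(vals, labs))
      ref <- suppressMessages(
        pROC::auc(pROC::roc(labs, vals, direction = "<", quiet = TRUE)))
      expect_equal(r$auc, as.numeric(ref))
    }
  })
})

test_that("degenerate ROC inputs raise errors", {
  expect_error(roc_auc(labeled_scores(1:4, rep(TRUE, 4))), "undefined ROC")
  expect_error(youden_cutoff(labeled_scores(rep(2, 5),
                                            c(TRUE, TRUE, FALSE, FALSE, TRUE))),
               "identical")
})

test_that("the Youden search matches brute force and prefers sensitivity on ties", {
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(8:30, 1)
      vals <- round(runif(n, 0, 100), 1)
      labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(labs)) < 2 || length(unique(vals)) < 2) next
      res <- youden_cutoff(labeled_scores(vals, labs))
      oracle <- brute_force_youden(vals, labs)
      expect_equal(res$j, oracle$jmax)
      expect_true(all(res$j >= oracle$j - 1e-12))
    }
  })
  # constructed J tie: cutoffs 2.5 and 4.5 both give J = 2/3; the lower
  # cutoff has sensitivity 1 and must win
  vals <- c(2, 3, 5, 1, 4, 6)
  labs <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  res <- youden_cutoff(labeled_scores(vals, labs))
  oracle <- brute_force_youden(vals, labs)
  expect_equal(sum(abs(oracle$j - oracle$jmax) < 1e-12), 2L)
  expect_equal(res$cutoff, 2.5)
  expect_equal(res$sensitivity, 1)
})

test_that("confusion matrices are exact and transform-invariant", {
  s <- labeled_scores(c(50, 40, 10, 5), c(TRUE, TRUE, FALSE, FALSE))
  cm <- confusion(s, 30)
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(2, 0, 2, 0))
  expect_equal(cm$sensitivity, 100)
  expect_equal(cm$specificity, 100)
  expect_equal(cm$accuracy, 100)

  # invariance under a strictly monotone transform of scores and cutoff
  withr::with_seed(43, {
    vals <- runif(20, 1, 99)
    labs <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    cut <- runif(1, 10, 90)
    a <- confusion(labeled_scores(vals, labs), cut)
    b <- confusion(labeled_scores(vals^3, labs), cut^3)
    expect_equal(c(a$tp, a$fp, a$tn, a$fn), c(b$tp, b$fp, b$tn, b$fn))
  })
})

test_that("Clopper-Pearson intervals match the exact binomial test", {
  expect_equal(round(clopper_pearson(10, 12), 1), c(lo = 51.6, hi = 97.9))
  expect_equal(clopper_pearson(12, 12)[["hi"]], 100)
  expect_equal(clopper_pearson(0, 12)[["lo"]], 0)
  # independent oracle: binom.test's exact interval
  for (k in c(1, 5, 7, 9)) {
    expect_equal(unname(clopper_pearson(k, 10)),
                 100 * as.numeric(binom.test(k, 10)$conf.int),
                 tolerance = 1e-12)
  }
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(-1, 4), "k <= n")
})

test_that("Mann-Whitney exact path agrees with permutation enumeration", {
  x <- c(1.2, 3.4, 5.1, 9.9)
  y <- c(0.4, 2.2, 6.3, 7.7)
  res <- mann_whitney(x, y)
  expect_identical(res$method, "exact")

  # brute force: U for every C(8,4) relabeling of the pooled values
  pooled <- c(x, y)
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  combos <- combn(8, 4)
  u_all <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  u_obs <- u_stat(x, y)
  p_perm <- min(1, 2 * min(mean(u_all >= u_obs), mean(u_all <= u_obs)))
  expect_equal(res$p, p_perm)
  expect_equal(res$u, u_obs)

  # U follows the pair-count convention (matches wilcox.test's W)
  expect_equal(res$u, unname(wilcox.test(x, y)$statistic))
})

test_that("ties and identical samples fall back to the normal approximation", {
  z <- c(1, 2, 3, 4)
  res <- mann_whitney(z, z)
  expect_identical(res$method, "normal")
  expect_equal(res$p, 1)
  expect_equal(res$u, length(z)^2 / 2)
  # large untied samples also use the approximation
  big <- mann_whitney(seq(1, 30, length.out = 10) + 0.01, seq(1, 30))
  expect_identical(big$method, "normal")
  expect_true(big$p > 0 && big$p <= 1)
})

test_that("group summaries report mean, sd and sem per class", {
  s <- labeled_scores(c(2, 4, 6, 10), c(TRUE, TRUE, TRUE, FALSE))
  g <- group_summary(s)
  expect_equal(g$mean, c(4, 10))
  expect_equal(g$sd[1], 2)
  expect_equal(g$sem[1], 2 / sqrt(3))
  expect_true(is.na(g$sd[2]) && is.na(g$sem[2]))  # single-member class
})

test_that("Pearson correlation matches the covariance formula", {
  x <- 1:10
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  withr::with_seed(44, {
    a <- rnorm(10); b <- rnorm(10)
    direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_corr(a, b)$r, direct, tolerance = 1e-12)
  })
  expect_error(pearson_corr(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_corr(1:2, 2:3), "at least 3")
})

test_that("display rounding goes half away from zero", {
  expect_equal(display_round(36.25), 36.3)
  expect_equal(display_round(-1.25), -1.3)
  expect_equal(display_round(82.608, 1), 82.6)
  expect_equal(display_round(0.8484848, 2), 0.85)
})
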