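test_that("AUC equals the rank-based Mann-Whitney oracle", {
  expect_equal(auc_mann_whitney(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc_mann_whitney(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(8)
  for (i in 1:5) {
    sc <- sample(c(runif(150), round(runif(50), 1)))
    y <- rbinom(200, 1, 0.5)
    if (length(unique(y)) < 2) next
    u <- unname(stats::wilcox.test(sc[y == 1], sc[y == 0],
                                   exact = FALSE)$statistic)
    expect_equal(auc_mann_whitney(sc, y), u / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-12)
  }
  expect_true(is.na(auc_mann_whitney(runif(5), rep(1, 5))))
})

test_that("DeLong test behaves on degenerate and antisymmetric inputs", {
  set.seed(9)
  y <- rep(c(0, 1), 30)
  s <- runif(60) + 0.5 * y
  self <- delong_test(s, s, y)
  expect_equal(self$p, 1)
  expect_true(self$degenerate)
  # perfect scorer against its negation
  s2 <- c(runif(30, 0, 0.4), runif(30, 0.6, 1))
  y2 <- rep(c(0, 1), each = 30)
  d <- delong_test(s2, 1 - s2, y2)
  expect_equal(d$auc_a, 1)
  expect_equal(d$auc_b, 0)
  expect_lt(d$p, 0.001)
})

test_that("DeLong p values match the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  y <- rbinom(80, 1, 0.5)
  a <- runif(80) + 0.4 * y
  b <- 0.6 * a + 0.4 * runif(80)
  mine <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("McNemar matches the continuity-corrected hand formula", {
  # discordant counts b = 10, c = 2 -> (|10-2|-1)^2/12 = 49/12
  pa <- c(rep(1, 10), rep(0, 2), rep(1, 20))
  pb <- c(rep(0, 10), rep(1, 2), rep(1, 20))
  y <- rep(1, 32)
  r <- paired_tests(pa, pb, y)
  expect_equal(r$mcnemar_statistic, 49 / 12, tolerance = 1e-9)
  expect_equal(r$mcnemar_p, 0.0433, tolerance = 1e-3)
  # symmetry and identical-vector degeneracy
  r2 <- paired_tests(pb, pa, y)
  expect_equal(r2$mcnemar_p, r$mcnemar_p)
  r3 <- paired_tests(pa, pa, y)
  expect_equal(r3$mcnemar_p, 1)
  expect_true(r3$degenerate)
})

test_that("threshold sweeps are monotone with correct extremes", {
  set.seed(11)
  y <- rep(c(0, 1), each = 25)
  s <- c(runif(25, 0, 0.6), runif(25, 0.4, 1))
  sw <- threshold_sweep(s, y)$sweep
  expect_true(all(diff(sw$sensitivity) <= 1e-12))
  expect_equal(sw$sensitivity[1], 1)
  expect_equal(sw$specificity[1], 0)
  expect_equal(sw$sensitivity[nrow(sw)], 0)
  expect_equal(sw$specificity[nrow(sw)], 1)
  # perfect scorer: thresholds between the classes give F1 = 1 for both
  sp <- c(runif(25, 0, 0.3), runif(25, 0.7, 1))
  swp <- threshold_sweep(sp, y)$sweep
  mid <- swp$threshold > 0.35 & swp$threshold < 0.65
  expect_true(all(swp$f1_malignant[mid] == 1))
  expect_true(all(swp$f1_benign[mid] == 1))
  # operating point: largest admissible threshold with full sensitivity
  op <- threshold_sweep(sp, y, sens_target = 1, max_threshold = 0.5)$operating_point
  expect_true(op$sensitivity == 1)
  expect_gte(op$threshold, 0.3)
})

test_that("evaluate_scores reports the worked confusion example", {
  m <- evaluate_scores(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5)
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(sum(m$confusion), 4)
  # no positives: AUC missing, not zero
  m2 <- evaluate_scores(runif(5), rep(0, 5))
  expect_true(is.na(m2$auc))
})
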