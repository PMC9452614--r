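make_batch_table <- function(n = 80, p = 15, shift = 2, scale = 1.6,
                             seed = 11) {
  set.seed(seed)
  batch <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[batch == "b", ] <- X[batch == "b", ] * scale + shift
  tab <- data.frame(case_id = sprintf("c%03d", 1:n), batch = batch,
                    label = rep(c("benign", "malignant"), n / 2), X,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab)[-(1:3)] <- paste0("f", seq_len(p))
  tab
}

test_that("a single batch yields the identity transform", {
  tab <- make_batch_table()
  tab$batch <- "a"
  m <- combat_fit(tab)
  expect_true(m$identity)
  expect_true(all(m$gamma_star == 0))
  expect_true(all(abs(m$delta_star2 - 1) < 1e-8))
  expect_identical(combat_apply(m, tab), tab)
})

test_that("a pure location shift is removed on large equal batches", {
  # equal within-batch variance, shift-only batch effect: the closed-form
  # adjustment recenters batches and leaves the within-batch variance
  tab <- make_batch_table(n = 400, p = 10, shift = 3, scale = 1, seed = 21)
  out <- combat_apply(combat_fit(tab), tab)
  X <- as.matrix(out[, -(1:3)])
  a <- X[tab$batch == "a", ]; b <- X[tab$batch == "b", ]
  se <- sqrt(apply(a, 2, var) / nrow(a) + apply(b, 2, var) / nrow(b))
  expect_true(all(abs(colMeans(a) - colMeans(b)) < 3 * se))
  expect_equal(mean(apply(X, 2, var)), 1, tolerance = 0.1)
})

test_that("the EB fixed point converges quickly and stays positive", {
  tab <- make_batch_table()
  m <- combat_fit(tab)
  expect_lte(m$n_iter, 100)
  expect_true(all(m$delta_star2 > 0))
})

test_that("implementation matches the reference empirical-Bayes ComBat", {
  skip_if_not_installed("sva")
  tab <- make_batch_table(n = 60, p = 20, seed = 31)
  mine <- as.matrix(combat_apply(combat_fit(tab), tab)[, -(1:3)])
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(as.matrix(tab[, -(1:3)])), batch = tab$batch,
                par.prior = TRUE)))
  expect_equal(mine, ref, ignore_attr = TRUE, tolerance = 1e-3)
})

test_that("refitting on corrected data finds nothing left to correct", {
  tab <- make_batch_table(n = 200, p = 12, seed = 41)
  out <- combat_apply(combat_fit(tab), tab)
  m2 <- combat_fit(out)
  expect_true(all(abs(m2$gamma_star) < 0.1))
  expect_true(all(abs(m2$delta_star2 - 1) < 0.15))
})

test_that("non-feature columns pass through untouched", {
  tab <- make_batch_table()
  out <- combat_apply(combat_fit(tab), tab)
  expect_identical(out$label, tab$label)
  expect_identical(out$case_id, tab$case_id)
  expect_identical(out$batch, tab$batch)
})

test_that("degenerate fits and unseen batches are refused", {
  tab <- make_batch_table(n = 20)
  tab1 <- tab; tab1$batch <- c("a", rep("b", 19))
  expect_error(combat_fit(tab1), "at least 2")
  tab2 <- tab; tab2$f1 <- 1
  expect_error(combat_fit(tab2), "f1")
  m <- combat_fit(tab)
  tab3 <- tab; tab3$batch[1] <- "zz"
  expect_error(combat_apply(m, tab3), "unseen")
})

test_that("label protection keeps the class effect out of the batch estimate", {
  tab <- make_batch_table(n = 200, p = 10, shift = 2, scale = 1, seed = 51)
  cls <- tab$label == "malignant"
  tab[cls, -(1:3)] <- tab[cls, -(1:3)] + 3
  out <- combat_apply(combat_fit(tab, protect = "label"), tab)
  gap <- colMeans(as.matrix(out[cls, -(1:3)])) -
    colMeans(as.matrix(out[!cls, -(1:3)]))
  expect_equal(mean(gap), 3, tolerance = 0.4)
})

test_that("harmonisation aligns phantom batches without erasing class signal", {
  feats <- small_cohort()$features
  out <- combat_harmonize(feats)
  fc <- setdiff(colnames(feats), c("case_id", "batch", "label"))
  pv <- sapply(fc, function(f) {
    x <- out[[f]]
    if (stats::sd(x) == 0) return(1)
    stats::t.test(x[out$batch == 1], x[out$batch == 2])$p.value
  })
  expect_lte(mean(pv < 0.05), 0.05)
  mal <- out$label == "malignant"
  expect_lt(stats::wilcox.test(out$glcm_contrast[mal],
                               out$glcm_contrast[!mal])$p.value, 0.05)
})
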