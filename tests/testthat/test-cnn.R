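test_that("the network has the stated block topology", {
  m <- build_cnn(64)
  types <- sapply(m$layers, `[[`, "type")
  block <- c("conv", "batchnorm", "relu", "maxpool", "dropout")
  expect_identical(types, c(rep(block, 3), "flatten", "dense", "relu",
                            "dropout", "dense", "sigmoid"))
  expect_equal(ncol(m$params$dense1_W), 8 * 8 * 32)
  expect_equal(nrow(m$params$dense1_W), 32)
})

test_that("forward passes emit probabilities and differ across init seeds", {
  set.seed(1)
  X <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  m1 <- build_cnn(32, widths = c(4, 8, 8), seed = 1)
  m2 <- build_cnn(32, widths = c(4, 8, 8), seed = 2)
  p1 <- predict(m1, X); p2 <- predict(m2, X)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_false(isTRUE(all.equal(p1, p2)))
})

test_that("backpropagation matches finite differences", {
  set.seed(3)
  m <- build_cnn(8, widths = c(2, 3, 2), dense_units = 4,
                 dropout = c(0, 0, 0, 0), seed = 3)
  N <- 4
  X <- array(rnorm(8 * 8 * N), c(8, 8, N))
  y <- c(1, 0, 1, 0); w <- rep(1, N)
  fwd <- liporad:::cnn_forward(m, X, train = TRUE)
  gr <- liporad:::cnn_backward(m, fwd, y, w)
  loss_at <- function(mm) {
    f <- liporad:::cnn_forward(mm, X, train = TRUE)
    liporad:::cnn_loss(f$prob, y, w)
  }
  h <- 1e-5
  for (pn in c("conv1_W", "bn2_gamma", "dense1_W", "dense2_b")) {
    i <- sample(length(m$params[[pn]]), 1)
    mp <- m; mp$params[[pn]][i] <- mp$params[[pn]][i] + h
    mm_ <- m; mm_$params[[pn]][i] <- mm_$params[[pn]][i] - h
    fd <- (loss_at(mp) - loss_at(mm_)) / (2 * h)
    expect_equal(unname(gr[[pn]][i]), fd, tolerance = 1e-2)
  }
})

test_that("augmentation preserves shape, identity limits, and pixel mass", {
  set.seed(4)
  img <- matrix(rnorm(48 * 48), 48, 48)
  out <- augment_slice(img, seed = 5)
  expect_identical(dim(out), dim(img))
  # degenerate config returns the input unchanged
  expect_identical(augment_slice(img, seed = 6, flip = FALSE, zoom = 0,
                                 rotate = 0, shift = 0), img)
  # shift-only: pixel mass approximately preserved under edge replication
  img_pos <- matrix(runif(48 * 48, 1, 2), 48, 48)
  sh <- augment_slice(img_pos, seed = 7, flip = FALSE, zoom = 0, rotate = 0,
                      shift = 0.1)
  expect_lt(abs(sum(sh) - sum(img_pos)) / sum(img_pos), 0.1)
  # determinism per seed
  expect_identical(augment_slice(img, seed = 8), augment_slice(img, seed = 8))
})

test_that("the CNN can learn a small texture discrimination task", {
  set.seed(7)
  n <- 60
  X <- array(0, c(32, 32, n))
  y <- rep(0:1, each = n / 2)
  for (i in 1:n) {
    img <- matrix(rnorm(32 * 32), 32)
    if (y[i] == 1) for (b in 1:4) {
      cx <- runif(1, 8, 24); cy <- runif(1, 8, 24)
      gx <- outer(1:32 - cx, rep(1, 32)); gy <- outer(rep(1, 32), 1:32 - cy)
      img <- img + 2.5 * exp(-(gx^2 + gy^2) / 8)
    }
    X[, , i] <- zscore_normalize(img)
  }
  m <- build_cnn(32, seed = 2)
  m <- cnn_fit(m, X, y, epochs = 15, seed = 5)
  pr <- predict(m, X)
  expect_gte(mean((pr >= 0.5) == y), 0.9)
})

test_that("slice datasets respect grouping and z-scoring", {
  co <- small_cohort()
  ds <- build_slice_dataset(co$manifest[1:6, ], out_size = 32)
  expect_true(all(ds$case_id %in% co$manifest$case_id[1:6]))
  for (s in seq_len(min(dim(ds$X)[3], 5))) {
    expect_equal(mean(ds$X[, , s]), 0, tolerance = 1e-6)
    expect_equal(sqrt(mean(ds$X[, , s]^2)), 1, tolerance = 1e-6)
  }
  # case-level AUC equals the Mann-Whitney oracle on aggregated scores
  scores <- tapply(runif(length(ds$case_id)), ds$case_id, mean)
  labs <- tapply(ds$label, ds$case_id, `[`, 1)
  u <- unname(stats::wilcox.test(scores[labs == "malignant"],
                                 scores[labs == "benign"],
                                 exact = FALSE)$statistic)
  expect_equal(auc_mann_whitney(as.numeric(scores), as.character(labs)),
               u / (sum(labs == "malignant") * sum(labs == "benign")),
               tolerance = 1e-12)
})
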