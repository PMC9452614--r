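test_that("GLCM reproduces the 2x2 worked example and its invariants", {
  L <- array(0L, c(2, 2, 1))
  L[1, 1, 1] <- 1L; L[1, 2, 1] <- 1L; L[2, 1, 1] <- 1L; L[2, 2, 1] <- 2L
  g <- build_glcm(qv(L, 2), 0)
  expect_equal(g, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  expect_equal(sum(g^2), 0.375)
  # constant lesion: single diagonal entry
  Lc <- array(0L, c(4, 4, 2)); Lc[2:3, 2:3, ] <- 1L
  gc_ <- build_glcm(qv(Lc, 1), 45)
  expect_equal(gc_, matrix(1, 1, 1))
})

test_that("GLRLM counts runs and conserves voxel mass", {
  L <- array(0L, c(1, 3, 1)); L[1, , 1] <- c(1L, 1L, 2L)
  M <- build_glrlm(qv(L, 2), 0)
  expect_equal(M, matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  Lr <- array(0L, c(1, 7, 1)); Lr[1, , 1] <- 3L
  Mr <- build_glrlm(qv(Lr, 3), 0)
  expect_equal(Mr[3, 7], 1)
  expect_equal(sum(Mr), 1)
  # mass: sum over l * M(i,l) = masked voxels, any direction
  set.seed(6)
  L2 <- array(sample(0:3, 5 * 5 * 3, replace = TRUE), c(5, 5, 3))
  for (dir in c(0, 45, 90, 135)) {
    M2 <- build_glrlm(qv(L2, 3), dir)
    expect_equal(sum(sweep(M2, 2, seq_len(ncol(M2)), `*`)), sum(L2 > 0))
  }
})

test_that("GLSZM zones use 26-connectivity (corner contact joins)", {
  Lc <- array(0L, c(5, 5, 4)); Lc[2:4, 2:4, 2:3] <- 2L
  M <- build_glszm(qv(Lc, 2))
  expect_equal(M[2, 18], 1)       # one zone of 18 voxels
  expect_equal(sum(M), 1)
  # two voxels touching only at a corner are ONE zone
  L <- array(0L, c(2, 2, 2)); L[1, 1, 1] <- 1L; L[2, 2, 2] <- 1L
  M2 <- build_glszm(qv(L, 1))
  expect_equal(M2[1, 2], 1)
  expect_equal(sum(M2), 1)
})

test_that("NGTDM reproduces the hand-enumerated centre-voxel example", {
  L <- array(1L, c(3, 3, 3)); L[2, 2, 2] <- 2L
  ng <- build_ngtdm(qv(L, 2))
  expect_equal(ng$s[2], 1)                     # |2 - mean(26 ones)| = 1
  orc <- oracle_ngtdm(L, 2)
  expect_equal(ng$s, orc$s)
  expect_equal(ng$p, orc$p)
  expect_equal(sum(ng$p), 1)
  # constant lesion: all s_i zero
  Lc <- array(0L, c(4, 4, 3)); Lc[2:3, 2:3, 1:2] <- 1L
  expect_true(all(build_ngtdm(qv(Lc, 1))$s == 0))
})

test_that("all four builders agree with brute-force oracles on random grids", {
  set.seed(7)
  for (t in 1:25) {
    Ng <- sample(2:4, 1)
    L <- array(sample(0:Ng, 5 * 5 * 3, replace = TRUE), c(5, 5, 3))
    if (sum(L > 0) < 2) next
    q <- qv(L, Ng)
    for (dir in c(0, 45, 90, 135)) {
      off <- liporad:::direction_offset(dir)
      mine <- tryCatch(build_glcm(q, dir), error = function(e) NULL)
      if (!is.null(mine)) expect_equal(mine, oracle_glcm(L, Ng, off))
      expect_equal(build_glrlm(q, dir), oracle_glrlm(L, Ng, dir))
    }
    zo <- oracle_zones(L)
    expect_equal(build_glszm(q), zone_table(zo[, 1], zo[, 2], Ng))
    orc <- oracle_ngtdm(L, Ng)
    mine_n <- build_ngtdm(q)
    expect_equal(mine_n$s, orc$s, tolerance = 1e-12)
    expect_equal(mine_n$p, orc$p, tolerance = 1e-12)
  }
})

test_that("matrix builders respect their geometric invariances", {
  set.seed(8)
  L <- array(sample(0:3, 6 * 6 * 4, replace = TRUE), c(6, 6, 4))
  q <- qv(L, 3)
  # slice order irrelevant for in-plane GLCM/GLRLM
  perm <- c(3, 1, 4, 2)
  qp <- qv(L[, , perm], 3)
  for (dir in c(0, 90)) {
    expect_equal(build_glcm(q, dir), build_glcm(qp, dir))
    expect_equal(build_glrlm(q, dir), build_glrlm(qp, dir))
  }
  # translation irrelevant for GLSZM/NGTDM
  Lt <- array(0L, c(8, 8, 6))
  Lt[2:7, 3:8, 2:5] <- L
  qt <- qv(Lt, 3)
  expect_equal(build_glszm(q), build_glszm(qt))
  expect_equal(build_ngtdm(q)$s, build_ngtdm(qt)$s)
  expect_equal(build_ngtdm(q)$p, build_ngtdm(qt)$p)
})

test_that("GLCM normalisation and symmetry hold on quantized phantom data", {
  spec <- test_spec(n_cases = 2, seed = 51)
  v <- resample_isotropic(generate_case(spec, 1), 1)
  for (ng in c(8, 16)) {
    q <- equal_probability_quantize(v, ng)
    for (dir in c(0, 45, 90, 135)) {
      P <- build_glcm(q, dir)
      expect_equal(sum(P), 1, tolerance = 1e-9)
      expect_equal(P, t(P), tolerance = 1e-12)
    }
    M <- build_glszm(q)
    expect_equal(sum(sweep(M, 2, seq_len(ncol(M)), `*`)), sum(q$levels > 0))
  }
})
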