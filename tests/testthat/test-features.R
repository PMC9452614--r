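test_that("the catalog has 92 uniquely named features in fixed family sizes", {
  cat_ <- feature_catalog()
  expect_equal(nrow(cat_), 92)
  expect_false(anyDuplicated(cat_$name) > 0)
  sizes <- table(cat_$family)
  expect_equal(unname(sizes[c("shape", "histogram", "glcm", "glrlm",
                              "glszm", "ngtdm", "gabor")]),
               c(14, 14, 21, 13, 13, 5, 12), ignore_attr = TRUE)
})

test_that("shape features are exact on boxes and near-ideal on spheres", {
  box <- array(FALSE, c(8, 10, 12)); box[2:6, 2:8, 2:10] <- TRUE
  bf <- shape_features(box, c(1, 2, 3))
  expect_equal(unname(bf["shape_volume_mm3"]), 5 * 7 * 9 * 6)
  sph <- sphere_mask(20)
  sf <- shape_features(sph, c(1, 1, 1))
  expect_gte(unname(sf["shape_sphericity"]), 0.95)
  expect_lte(unname(sf["shape_sphericity"]), 1.0)
  expect_equal(unname(sf["shape_max_diameter_mm"]), 40, tolerance = 0.05)
  # prolate ellipsoid semi-axes (20, 10, 10): elongation ~ 0.5
  d <- c(45, 45, 45); ctr <- c(23, 23, 23)
  gx <- slice.index(array(0, d), 1) - ctr[1]
  gy <- slice.index(array(0, d), 2) - ctr[2]
  gz <- slice.index(array(0, d), 3) - ctr[3]
  el <- (gx / 20)^2 + (gy / 10)^2 + (gz / 10)^2 <= 1
  dim(el) <- d
  ef <- shape_features(el, c(1, 1, 1))
  expect_equal(unname(ef["shape_elongation"]), 0.5, tolerance = 0.05)
  expect_error(shape_features(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("histogram features match moment conventions", {
  hc <- histogram_features(rep(5, 10))
  expect_equal(unname(hc[c("hist_variance", "hist_entropy", "hist_uniformity")]),
               c(0, 0, 1))
  expect_equal(unname(histogram_features(c(1, 2, 3))["hist_skewness"]), 0)
  set.seed(2)
  hn <- histogram_features(rnorm(1e4))
  expect_equal(unname(hn["hist_skewness"]), 0, tolerance = 0.1)
  expect_equal(unname(hn["hist_kurtosis"]), 0, tolerance = 0.2)
  expect_error(histogram_features(numeric(0)), "empty")
})

test_that("GLCM features agree with hand expansion of the worked example", {
  L <- array(0L, c(2, 2, 1))
  L[1, 1, 1] <- 1L; L[1, 2, 1] <- 1L; L[2, 1, 1] <- 1L; L[2, 2, 1] <- 2L
  gf <- glcm_features(build_glcm(qv(L, 2), 0))
  expect_equal(unname(gf["glcm_contrast"]), 0.5)
  expect_equal(unname(gf["glcm_energy"]), 0.375)
  expect_equal(unname(gf["glcm_dissimilarity"]), 0.5)
  expect_equal(unname(gf["glcm_max_probability"]), 0.5)
  # constant image conventions
  gfc <- glcm_features(matrix(1, 1, 1))
  expect_equal(unname(gfc[c("glcm_energy", "glcm_entropy", "glcm_contrast",
                            "glcm_max_probability", "glcm_correlation")]),
               c(1, 0, 0, 1, 1))
})

test_that("NGTDM features obey the degenerate-lesion conventions", {
  Lc <- array(0L, c(4, 4, 3)); Lc[2:3, 2:3, 1:2] <- 1L
  nf <- ngtdm_features(build_ngtdm(qv(Lc, 1)))
  expect_equal(unname(nf["ngtdm_coarseness"]), 1e6)
  expect_equal(unname(nf[c("ngtdm_busyness", "ngtdm_complexity")]), c(0, 0))
})

test_that("run-length and size-zone features are exact on a two-run grid", {
  # M counts: level 1 has one run of 2, level 2 one run of 1 -> hand values
  M <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  f <- glrlm_features(M, Np = 3)
  expect_equal(unname(f["glrlm_sre"]), (1 / 4 + 1) / 2)
  expect_equal(unname(f["glrlm_lre"]), (4 + 1) / 2)
  expect_equal(unname(f["glrlm_run_percentage"]), 2 / 3)
  expect_equal(unname(f["glrlm_gln"]), (1 + 1) / 2)
  z <- glszm_features(M, Np = 3)
  expect_equal(unname(z["glszm_sae"]), (1 / 4 + 1) / 2)
})

test_that("Gabor features detect gratings and ignore the DC level", {
  d <- c(40, 40, 3)
  img <- array(0, d)
  for (i in 1:40) img[i, , ] <- sin(2 * pi * i / 6)   # varies along rows
  vg <- vol(img)
  gf <- gabor_features(vg)
  expect_equal(names(which.max(gf[1:6])), "gabor_mean_0")
  vg2 <- vg; vg2$intensities <- vg$intensities + 50
  expect_equal(gabor_features(vg2), gf, tolerance = 1e-9)
  # white noise: no strongly preferred orientation (lattice effects allowed)
  set.seed(9)
  vw <- vol(array(rnorm(40 * 40 * 6), c(40, 40, 6)))
  gw <- gabor_features(vw)[1:6]
  expect_lt(max(gw) / min(gw), 1.6)
})

test_that("extract_case emits 92 finite features with the stated invariances", {
  spec <- test_spec(n_cases = 2, seed = 61)
  v <- generate_case(spec, 1)
  cfg <- extraction_config(ng_levels = c(8, 16))
  f <- extract_case(v, cfg)
  expect_length(f, 92)
  expect_identical(names(f), feature_catalog()$name)
  expect_true(all(is.finite(f)))
  # intensity shift: only location-dependent histogram features change
  v2 <- v; v2$intensities <- v$intensities + 100
  f2 <- extract_case(v2, cfg)
  changed <- names(f)[abs(f2 - f) > 1e-8]
  expect_true(all(changed %in% c("hist_mean", "hist_median", "hist_min",
                                 "hist_max", "hist_p10", "hist_p90",
                                 "hist_energy")))
  # doubling spacing on a fixed array: diameter x2, volume x8
  v3 <- v; v3$spacing <- c(2, 2, 2)
  f3 <- extract_case(v3, extraction_config(target_spacing = 2,
                                           ng_levels = c(8, 16)))
  expect_equal(unname(f3["shape_max_diameter_mm"] / f["shape_max_diameter_mm"]),
               2, tolerance = 1e-9)
  expect_equal(unname(f3["shape_volume_mm3"] / f["shape_volume_mm3"]),
               8, tolerance = 1e-9)
})

test_that("cohort extraction is deterministic and order-equivariant", {
  co <- small_cohort()
  tab <- co$features
  expect_equal(dim(tab), c(20, 3 + 92))
  expect_true(all(is.finite(as.matrix(tab[, -(1:3)]))))
  man2 <- co$manifest[c(3, 1, 2), ]
  tab2 <- extract_cohort(man2, extraction_config(ng_levels = c(8, 16)))
  expect_equal(tab2[, -(1:3)], tab[c(3, 1, 2), -(1:3)], ignore_attr = TRUE,
               tolerance = 1e-12)
  # re-running is byte-identical
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  extract_cohort(co$manifest[1:2, ], extraction_config(ng_levels = 8),
                 out_csv = f1)
  extract_cohort(co$manifest[1:2, ], extraction_config(ng_levels = 8),
                 out_csv = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("texture features separate the phantom classes", {
  feats <- small_cohort()$features
  mal <- feats$label == "malignant"
  p_glcm <- stats::wilcox.test(feats$glcm_contrast[mal],
                               feats$glcm_contrast[!mal])$p.value
  p_ngtdm <- stats::wilcox.test(feats$ngtdm_strength[mal],
                                feats$ngtdm_strength[!mal])$p.value
  expect_lt(min(p_glcm, p_ngtdm), 0.05)
})
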