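test_that("case generation is deterministic and masks are valid lesions", {
  spec <- test_spec(n_cases = 6, seed = 11)
  v1 <- generate_case(spec, 3)
  v2 <- generate_case(spec, 3)
  expect_identical(v1$intensities, v2$intensities)
  expect_identical(v1$mask, v2$mask)
  for (i in 1:4) {
    v <- generate_case(spec, i)
    expect_gte(sum(v$mask), 27)
    expect_true(liporad:::single_component_26(v$mask))
  }
})

test_that("labels and batches are stratified and balanced", {
  spec <- phantom_spec(n_cases = 40, class_balance = 0.5, n_batches = 2,
                       confounding = 0, seed = 5, grid_shape = c(28, 28, 26),
                       lesion_semiaxes = c(5, 8))
  expect_equal(sum(spec$label == "malignant"), 20)
  expect_equal(sum(spec$label == "benign"), 20)
  # round-robin within class: batch and class independent by construction
  tab <- table(spec$label, spec$batch_assignment)
  expect_true(all(tab == 10))
})

test_that("a lesion too large for the grid names the offending axis", {
  spec <- test_spec(n_cases = 2, seed = 3, lesion_semiaxes = c(30, 30))
  expect_error(generate_case(spec, 1), "axis")
})

test_that("batch gain shows up as the expected masked-intensity ratio", {
  # pure gain spec: no offset/blur and no scanner jitter, so the batch-2 /
  # batch-1 ratio of mean masked intensities estimates the gain ratio
  spec <- phantom_spec(n_cases = 56, class_balance = 0.5, n_batches = 2,
                       confounding = 0, seed = 42,
                       grid_shape = c(24L, 24L, 20L), lesion_semiaxes = c(4, 6),
                       batch_gain = c(1, 1.5), batch_offset = c(0, 0),
                       batch_blur_sigma = c(0, 0), case_gain_sd = 0,
                       case_offset_sd = 0, case_blur_sd = 0,
                       class_texture_gap = 0)
  means <- sapply(seq_len(spec$n_cases), function(i) {
    v <- generate_case(spec, i)
    mean(v$intensities[v$mask])
  })
  ratio <- mean(means[spec$batch_assignment == 2]) /
    mean(means[spec$batch_assignment == 1])
  expect_equal(ratio, 1.5, tolerance = 0.1)
})

test_that("zero texture gap makes the label uninformative", {
  spec <- test_spec(n_cases = 30, seed = 9, class_texture_gap = 0,
                    batch_gain = c(1, 1), batch_offset = c(0, 0),
                    batch_blur_sigma = c(0, 0), case_gain_sd = 0,
                    case_offset_sd = 0, case_blur_sd = 0)
  vars <- sapply(seq_len(spec$n_cases), function(i) {
    v <- generate_case(spec, i)
    stats::var(v$intensities[v$mask])
  })
  p <- stats::wilcox.test(vars[spec$label == "malignant"],
                          vars[spec$label == "benign"])$p.value
  expect_gt(p, 0.01)
})

test_that("cohort writing produces the expected files and round-trips", {
  dir <- file.path(tempdir(), "phantom-io")
  unlink(dir, recursive = TRUE)
  spec <- test_spec(n_cases = 5, seed = 21)
  man <- generate_cohort(spec, dir)
  expect_equal(length(list.files(dir, pattern = "nii.gz$")), 10)
  csv <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(csv), 5)
  expect_identical(colnames(csv), c("case_id", "batch", "label"))
  v_mem <- generate_case(spec, 2)
  v_disk <- read_case(man$image[2], man$mask[2])
  expect_equal(v_disk$intensities, unclass(v_mem$intensities),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_identical(v_disk$mask, v_mem$mask)
  expect_equal(v_disk$spacing, v_mem$spacing)
  # refuses to clobber
  expect_error(generate_cohort(spec, dir), "overwrite")
  expect_silent(generate_cohort(spec, dir, overwrite = TRUE))
})

test_that("a 20% gain difference shifts raw intensity features detectably", {
  dir <- file.path(tempdir(), "phantom-gain")
  spec <- test_spec(n_cases = 16, seed = 77, batch_gain = c(1, 1.25),
                    batch_offset = c(0, 0), batch_blur_sigma = c(0, 0),
                    case_gain_sd = 0, case_offset_sd = 0, case_blur_sd = 0)
  man <- generate_cohort(spec, dir, overwrite = TRUE)
  feats <- extract_cohort(man, extraction_config(ng_levels = 8))
  ps <- sapply(c("hist_mean", "hist_median", "hist_p90", "hist_energy"),
               function(f) stats::t.test(feats[[f]][feats$batch == 1],
                                         feats[[f]][feats$batch == 2])$p.value)
  expect_true(any(ps < 0.01))
})
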