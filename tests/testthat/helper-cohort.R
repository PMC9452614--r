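# Shared small-cohort fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

test_spec <- function(n_cases = 20, seed = 101, lesion_semiaxes = c(5, 8),
                      ...) {
  phantom_spec(n_cases = n_cases, class_balance = 0.5, n_batches = 2,
               seed = seed, grid_shape = c(28L, 28L, 26L),
               voxel_spacing = c(1, 1, 1), lesion_semiaxes = lesion_semiaxes,
               ...)
}

# a 20-case cohort on disk + its 92-feature table (2 quantization levels for
# speed); built lazily, reused across test files
small_cohort <- function() {
  if (!is.null(.fixtures$cohort)) return(.fixtures$cohort)
  dir <- file.path(tempdir(), "liporad-test-cohort")
  spec <- test_spec(n_cases = 20, seed = 101)
  man <- generate_cohort(spec, dir, overwrite = TRUE)
  feats <- extract_cohort(man, extraction_config(ng_levels = c(8, 16)))
  .fixtures$cohort <- list(spec = spec, dir = dir, manifest = man,
                           features = feats)
  .fixtures$cohort
}

# synthetic (non-imaging) feature table for classifier tests
synth_features <- function(n = 40, p = 6, shift = 2, seed = 7) {
  set.seed(seed)
  lab <- rep(c("benign", "malignant"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[lab == "malignant", 1:2] <- X[lab == "malignant", 1:2] + shift
  tab <- data.frame(case_id = sprintf("c%03d", seq_len(n)),
                    batch = rep(c(1, 2), n / 2), label = lab, X,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab)[-(1:3)] <- paste0("f", seq_len(p))
  tab
}
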