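# End-to-end orchestration: simulate -> extract -> harmonize -> benchmark ->
# CNN -> report, with a resolved-config record for provenance.

#' Run the full phantom benchmark pipeline
#'
#' Generates (or reuses) a phantom cohort, extracts the 92-feature table,
#' benchmarks the four classifiers on raw versus per-fold ComBat-harmonised
#' features, optionally runs the CNN arm, and writes a report bundle
#' (`features.csv`, `features_corrected.csv`, `report.json`, `report.md`,
#' `roc_<model>.tsv`, `config.json`) into `out_dir`.
#'
#' @param spec a [phantom_spec()] (e.g. from [phantom_preset()]).
#' @param out_dir output directory.
#' @param seed integer master seed (cohort, CV and model seeds derive from
#'   it unless fixed in `spec`).
#' @param k cross-validation folds.
#' @param config extraction configuration.
#' @param grids classifier hyperparameter grids.
#' @param run_cnn include the CNN arm.
#' @param cnn_size,cnn_epochs CNN slice size and training epochs.
#' @param overwrite overwrite an existing cohort in `out_dir`.
#' @param verbose log progress.
#' @return list with `features`, `benchmark`, `cnn_scores` (or NULL),
#'   `report` (the JSON-ready list), invisibly.
#' @export
run_pipeline <- function(spec = phantom_preset("paper-like"), out_dir,
                         seed = 1L, k = 10, config = extraction_config(),
                         grids = default_grids(), run_cnn = TRUE,
                         cnn_size = 64, cnn_epochs = 20,
                         overwrite = FALSE, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say("simulating ", spec$n_cases, "-case phantom cohort")
  cohort_dir <- file.path(out_dir, "cohort")
  manifest <- generate_cohort(spec, cohort_dir, overwrite = overwrite)
  say("extracting radiomic features")
  features <- extract_cohort(manifest, config)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  corrected <- combat_harmonize(features)
  utils::write.csv(corrected, file.path(out_dir, "features_corrected.csv"),
                   row.names = FALSE)
  say("benchmarking classifiers (raw vs harmonised, k = ", k, ")")
  bench <- run_benchmark(features, k = k, seed = derive_seed(seed, 11L),
                         grids = grids)
  cnn_scores <- NULL
  if (run_cnn) {
    say("training CNN arm")
    ds <- build_slice_dataset(manifest, out_size = cnn_size)
    cnn_scores <- cnn_cross_validate(ds, bench$plan, epochs = cnn_epochs,
                                     seed = derive_seed(seed, 12L))
  }
  report <- build_report(spec, bench, cnn_scores, seed, k, config)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report_md(report), file.path(out_dir, "report.md"))
  for (cl in unique(bench$grid$classifier)) {
    sw <- threshold_sweep(bench$arms$corrected$scores[[cl]],
                          bench$arms$corrected$scores$label)$sweep
    utils::write.table(sw, file.path(out_dir, paste0("roc_", cl, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  cfg <- list(preset = list(n_cases = spec$n_cases, n_batches = spec$n_batches,
                            confounding = spec$confounding,
                            class_texture_gap = spec$class_texture_gap,
                            seed = spec$seed),
              master_seed = seed, k = k,
              ng_levels = config$ng_levels, directions = config$directions,
              gabor_wavelengths = GABOR_WAVELENGTHS,
              gabor_orientations = GABOR_ORIENTATIONS,
              run_cnn = run_cnn, cnn_size = cnn_size, cnn_epochs = cnn_epochs)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = features, benchmark = bench,
                 cnn_scores = cnn_scores, report = report))
}

build_report <- function(spec, bench, cnn_scores, seed, k, config) {
  grid <- bench$grid
  rows <- lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ]))
  delong <- lapply(seq_len(nrow(bench$delong)), function(i)
    as.list(bench$delong[i, ]))
  cnn <- NULL
  if (!is.null(cnn_scores)) {
    m <- evaluate_scores(cnn_scores$score, cnn_scores$label)
    per_fold <- sapply(sort(unique(cnn_scores$fold)), function(f) {
      sub <- cnn_scores[cnn_scores$fold == f, ]
      auc_mann_whitney(sub$score, sub$label)
    })
    cnn <- list(auc_mean = mean(per_fold, na.rm = TRUE),
                auc_sd = stats::sd(per_fold[!is.na(per_fold)]),
                sensitivity = m$sensitivity, specificity = m$specificity)
  }
  gbsw <- threshold_sweep(bench$arms$corrected$scores$gb,
                          bench$arms$corrected$scores$label)
  list(seeds = list(master = seed, cohort = spec$seed, cv = bench$plan$seed),
       k = k, n_cases = spec$n_cases,
       benchmark = rows, delong = delong, cnn = cnn,
       gb_operating_point = if (is.null(gbsw$operating_point)) NULL
       else as.list(gbsw$operating_point))
}

render_report_md <- function(report) {
  g <- do.call(rbind, lapply(report$benchmark, as.data.frame))
  lines <- c("# Phantom benchmark report", "",
             sprintf("Cases: %d; folds: %d; seeds: master %d, cohort %d, cv %d",
                     report$n_cases, report$k, report$seeds$master,
                     report$seeds$cohort, report$seeds$cv), "",
             "| dataset | classifier | AUC | sensitivity | specificity |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %.2f ± %.2f | %.2f ± %.2f | %.2f ± %.2f |",
                     g$dataset, toupper(g$classifier), g$auc_mean, g$auc_sd,
                     g$sens_mean, g$sens_sd, g$spec_mean, g$spec_sd))
  if (!is.null(report$cnn))
    lines <- c(lines, sprintf("| images | CNN | %.2f ± %.2f | %.2f | %.2f |",
                              report$cnn$auc_mean, report$cnn$auc_sd,
                              report$cnn$sensitivity, report$cnn$specificity))
  lines
}
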