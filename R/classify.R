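# The four classifier arms (LR, SVM, RF, GB), patient-grouped stratified
# cross-validation, inner-CV hyperparameter tuning, and the raw-vs-harmonised
# benchmark grid.

#' Default hyperparameter grids
#'
#' LR: ridge-penalised logistic regression, C in \{0.01, 0.1, 1, 10\}.
#' SVM: RBF kernel, C in \{0.1, 1, 10\}, gamma = (1/p) x \{0.1, 1, 10\}.
#' RF: 100/300 trees, depth unlimited/5/10. GB: 100/300 rounds, learning rate
#' 0.05/0.1, depth 2/3.
#'
#' @return named list of per-classifier grids.
#' @export
default_grids <- function() {
  list(
    lr = expand.grid(C = c(0.01, 0.1, 1, 10)),
    svm = expand.grid(C = c(0.1, 1, 10), gamma_mult = c(0.1, 1, 10)),
    rf = expand.grid(num_trees = c(100, 300), max_depth = c(0, 5, 10)),
    gb = expand.grid(nrounds = c(100, 300), eta = c(0.05, 0.1),
                     max_depth = c(2, 3))
  )
}

# A fast reduced grid for small cohorts and quick runs.
small_grids <- function() {
  list(lr = expand.grid(C = c(0.1, 1)),
       svm = expand.grid(C = c(1, 10), gamma_mult = 1),
       rf = expand.grid(num_trees = 100, max_depth = 0),
       gb = expand.grid(nrounds = 100, eta = 0.1, max_depth = 2))
}

#' Build a stratified, patient-grouped cross-validation plan
#'
#' Every case lands in exactly one fold; all rows sharing a `case_id` share a
#' fold; per-fold class proportions are within one case of the global
#' proportions. Deterministic given the seed.
#'
#' @param table data frame with `case_id` and `label` columns (repeated
#'   case_ids allowed, e.g. slice tables).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return object of class `cv_plan`: list with `k`, `seed`, and `fold`, a
#'   named integer vector over case ids.
#' @export
make_cv_plan <- function(table, k = 10, seed = 1L) {
  cases <- unique(table[, c("case_id", "label")])
  if (anyDuplicated(cases$case_id))
    stop("a case_id appears with more than one label")
  cnt <- table(cases$label)
  if (any(cnt < k))
    stop(sprintf("class '%s' has %d cases < k = %d; use a smaller k",
                 names(cnt)[which.min(cnt)], min(cnt), k))
  fold <- integer(nrow(cases))
  names(fold) <- cases$case_id
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(cases$label))) {
      idx <- which(cases$label == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- 1L + (offset + seq_along(idx) - 1L) %% k
      offset <- offset + length(idx)
    }
  })
  structure(list(k = as.integer(k), seed = as.integer(seed), fold = fold),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("CV plan: k =", x$k, "folds over", length(x$fold),
      "cases (seed", paste0(x$seed, ")"), "\n")
  print(table(fold = x$fold))
  invisible(x)
}

fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ <= 0] <- 1
  list(mean = mu, sd = sd_)
}

apply_standardizer <- function(sc, X) {
  sweep(sweep(X, 2, sc$mean), 2, sc$sd, `/`)
}

fit_one <- function(name, X, y01, pars, seed) {
  with_seed(seed, switch(name,
    lr = {
      lam <- 1 / (pars$C * nrow(X))
      glmnet::glmnet(X, y01, family = "binomial", alpha = 0,
                     lambda = c(lam * 4, lam, lam / 4))
    },
    svm = e1071::svm(X, factor(y01, 0:1), kernel = "radial", cost = pars$C,
                     gamma = pars$gamma_mult / ncol(X), probability = TRUE),
    rf = ranger::ranger(x = X, y = factor(y01, 0:1),
                        num.trees = pars$num_trees,
                        max.depth = if (pars$max_depth == 0) NULL else pars$max_depth,
                        probability = TRUE, num.threads = 1,
                        seed = seed),
    gb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = pars$eta,
                    max_depth = pars$max_depth, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y01),
      nrounds = pars$nrounds, verbose = 0),
    stop("unknown classifier: ", name)))
}

predict_one <- function(name, fit, pars, X) {
  switch(name,
    lr = as.numeric(stats::predict(fit, newx = X, type = "response",
                                   s = 1 / (pars$C * fit$nobs))),
    svm = {
      pr <- stats::predict(fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rf = stats::predict(fit, data = X, num.threads = 1)$predictions[, "1"],
    gb = stats::predict(fit, xgboost::xgb.DMatrix(X)))
}

#' Train one classifier with inner-CV hyperparameter selection
#'
#' LR and SVM receive features standardised by statistics learned on the
#' training rows only; RF and GB consume raw features. With more than one
#' grid row, hyperparameters are chosen by stratified `inner_k`-fold CV on
#' AUC.
#'
#' @param name one of `"lr"`, `"svm"`, `"rf"`, `"gb"`.
#' @param train feature table rows for training (must contain both classes).
#' @param grid hyperparameter data frame (defaults to [default_grids()]).
#' @param inner_k inner folds for tuning (default 3).
#' @param seed integer seed.
#' @return object of class `liporad_classifier`.
#' @export
train_classifier <- function(name, train, grid = default_grids()[[name]],
                             inner_k = 3, seed = 1L) {
  name <- match.arg(name, c("lr", "svm", "rf", "gb"))
  feats <- feature_columns(train)
  y01 <- as_binary_label(train$label)
  if (length(unique(y01)) < 2) stop("training rows contain a single class")
  X <- as.matrix(train[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  scaler <- NULL
  if (name %in% c("lr", "svm")) {
    scaler <- fit_standardizer(X)
    X <- apply_standardizer(scaler, X)
  }
  best <- grid[1, , drop = FALSE]
  if (nrow(grid) > 1) {
    inner <- make_cv_plan(data.frame(case_id = seq_len(nrow(X)),
                                     label = y01),
                          k = inner_k, seed = derive_seed(seed, 77L))
    fold <- inner$fold[as.character(seq_len(nrow(X)))]
    mean_auc <- sapply(seq_len(nrow(grid)), function(g) {
      aucs <- sapply(seq_len(inner_k), function(f) {
        tr <- fold != f; te <- !tr
        if (length(unique(y01[tr])) < 2 || length(unique(y01[te])) < 2)
          return(NA_real_)
        fit <- fit_one(name, X[tr, , drop = FALSE], y01[tr],
                       grid[g, , drop = FALSE], derive_seed(seed, g))
        auc_mann_whitney(predict_one(name, fit, grid[g, , drop = FALSE],
                                     X[te, , drop = FALSE]), y01[te])
      })
      mean(aucs, na.rm = TRUE)
    })
    best <- grid[which.max(mean_auc), , drop = FALSE]
  }
  fit <- fit_one(name, X, y01, best, derive_seed(seed, 991L))
  structure(list(name = name, fit = fit, scaler = scaler,
                 hyper = best, features = feats),
            class = "liporad_classifier")
}

#' Malignancy scores from a trained classifier
#'
#' @param object a `liporad_classifier`.
#' @param newdata feature table.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.liporad_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  if (!is.null(object$scaler)) X <- apply_standardizer(object$scaler, X)
  as.numeric(predict_one(object$name, object$fit, object$hyper, X))
}

#' Cross-validated out-of-fold scores for one feature table
#'
#' For each fold: optionally fit ComBat on the training rows only and apply
#' it to both training and held-out rows (leakage-safe harmonisation), train
#' each classifier on the training rows, and score the held-out rows.
#'
#' @param features feature table.
#' @param plan a [make_cv_plan()] plan covering the table's cases.
#' @param classifiers character vector among lr/svm/rf/gb.
#' @param harmonize fit-and-apply ComBat per training fold.
#' @param batch_column batch column used when harmonising.
#' @param protect optional column protected in the ComBat design (see
#'   [combat_fit()]).
#' @param grids named list of hyperparameter grids.
#' @param seed integer seed.
#' @return list with `scores` (case_id, label, fold, one score column per
#'   classifier) and `fold_metrics` (per classifier and fold: auc,
#'   sensitivity, specificity at 0.5).
#' @export
cross_validate <- function(features, plan, classifiers = c("lr", "svm", "rf", "gb"),
                           harmonize = FALSE, batch_column = "batch",
                           grids = default_grids(), seed = 1L,
                           protect = NULL) {
  stopifnot(inherits(plan, "cv_plan"))
  fold <- plan$fold[features$case_id]
  if (anyNA(fold)) stop("plan does not cover all cases in the table")
  scores <- data.frame(case_id = features$case_id, label = features$label,
                       fold = fold, stringsAsFactors = FALSE)
  for (cl in classifiers) scores[[cl]] <- NA_real_
  for (f in sort(unique(fold))) {
    tr_tab <- features[fold != f, , drop = FALSE]
    te_tab <- features[fold == f, , drop = FALSE]
    if (harmonize) {
      cb <- combat_fit(tr_tab, batch_column, protect = protect)
      tr_tab <- combat_apply(cb, tr_tab)
      te_tab <- combat_apply(cb, te_tab)
    }
    for (cl in classifiers) {
      mdl <- train_classifier(cl, tr_tab, grid = grids[[cl]],
                              seed = derive_seed(seed, f))
      scores[fold == f, cl] <- predict(mdl, te_tab)
    }
  }
  fm <- do.call(rbind, lapply(classifiers, function(cl) {
    do.call(rbind, lapply(sort(unique(fold)), function(f) {
      m <- evaluate_scores(scores[[cl]][fold == f], scores$label[fold == f])
      data.frame(classifier = cl, fold = f, auc = m$auc,
                 sensitivity = m$sensitivity, specificity = m$specificity)
    }))
  }))
  list(scores = scores, fold_metrics = fm)
}

#' Benchmark the four classifiers on raw versus harmonised features
#'
#' Runs patient-grouped stratified k-fold cross-validation twice — once on
#' the raw feature table, once with per-fold ComBat harmonisation — and
#' assembles the classifier x dataset grid of mean +/- SD AUC, sensitivity
#' and specificity, pairwise DeLong tests on the pooled out-of-fold scores,
#' and McNemar / chi-squared comparisons of the 0.5-threshold predictions.
#'
#' @param features raw feature table (columns case_id, batch, label, 92
#'   features).
#' @param k folds (default 10).
#' @param seed integer seed (CV plan and classifier seeds derive from it).
#' @param classifiers classifiers to run.
#' @param grids hyperparameter grids.
#' @param batch_column batch column for harmonisation.
#' @param protect optional column protected in the ComBat design (see
#'   [combat_fit()]).
#' @return object of class `liporad_benchmark`.
#' @export
run_benchmark <- function(features, k = 10, seed = 1L,
                          classifiers = c("lr", "svm", "rf", "gb"),
                          grids = default_grids(), batch_column = "batch",
                          protect = NULL) {
  plan <- make_cv_plan(features, k = k, seed = derive_seed(seed, 1L))
  arms <- list(
    raw = cross_validate(features, plan, classifiers, harmonize = FALSE,
                         batch_column, grids, seed = derive_seed(seed, 2L)),
    corrected = cross_validate(features, plan, classifiers, harmonize = TRUE,
                               batch_column, grids, seed = derive_seed(seed, 3L),
                               protect = protect))
  grid_rows <- do.call(rbind, lapply(names(arms), function(a) {
    fm <- arms[[a]]$fold_metrics
    do.call(rbind, lapply(classifiers, function(cl) {
      sub <- fm[fm$classifier == cl, ]
      data.frame(dataset = a, classifier = cl,
                 auc_mean = mean(sub$auc, na.rm = TRUE),
                 auc_sd = stats::sd(sub$auc[!is.na(sub$auc)]),
                 sens_mean = mean(sub$sensitivity, na.rm = TRUE),
                 sens_sd = stats::sd(sub$sensitivity[!is.na(sub$sensitivity)]),
                 spec_mean = mean(sub$specificity, na.rm = TRUE),
                 spec_sd = stats::sd(sub$specificity[!is.na(sub$specificity)]))
    }))
  }))
  labels <- arms$raw$scores$label
  delong <- do.call(rbind, lapply(classifiers, function(cl) {
    d <- delong_test(arms$corrected$scores[[cl]], arms$raw$scores[[cl]], labels)
    p <- paired_tests(as.integer(arms$corrected$scores[[cl]] >= 0.5),
                      as.integer(arms$raw$scores[[cl]] >= 0.5), labels)
    data.frame(classifier = cl, auc_corrected = d$auc_a, auc_raw = d$auc_b,
               delong_z = d$z, delong_p = d$p,
               mcnemar_p = p$mcnemar_p, chisq_p = p$chisq_p)
  }))
  structure(list(grid = grid_rows, delong = delong, arms = arms, plan = plan,
                 seed = seed), class = "liporad_benchmark")
}

#' @export
print.liporad_benchmark <- function(x, digits = 3, ...) {
  cat("Classifier benchmark (k =", x$plan$k, "grouped folds, seed",
      paste0(x$seed, ")"), "\n\n")
  g <- x$grid
  out <- data.frame(dataset = g$dataset, classifier = toupper(g$classifier),
                    AUC = sprintf("%.2f ± %.2f", g$auc_mean, g$auc_sd),
                    sensitivity = sprintf("%.2f ± %.2f", g$sens_mean, g$sens_sd),
                    specificity = sprintf("%.2f ± %.2f", g$spec_mean, g$spec_sd))
  print(out, row.names = FALSE)
  cat("\nDeLong corrected vs raw (pooled out-of-fold scores):\n")
  d <- x$delong
  print(data.frame(classifier = toupper(d$classifier),
                   AUC_corr = round(d$auc_corrected, digits),
                   AUC_raw = round(d$auc_raw, digits),
                   p = signif(d$delong_p, 2)), row.names = FALSE)
  invisible(x)
}
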