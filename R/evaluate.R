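# ROC / AUC machinery, DeLong correlated-AUC test, paired prediction tests,
# and decision-threshold sweeps. The positive class is "malignant".

as_binary_label <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels > 0))
  as.integer(labels == "malignant")
}

#' Area under the ROC curve (Mann-Whitney construction)
#'
#' Mean over all positive/negative pairs of the indicator that the positive
#' scores higher, ties counted 1/2. Returns `NA` when either class is absent.
#'
#' @param scores numeric malignancy scores.
#' @param labels class labels (`"malignant"`/`"benign"` or 0/1).
#' @return AUC in \[0, 1\], or `NA_real_` if undefined.
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- as_binary_label(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}

# DeLong structural components: for each positive, mean placement against all
# negatives (V10); for each negative, against all positives (V01).
delong_components <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  psi <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same cases using
#' the covariance of their structural components; two-sided normal p value
#' for the paired difference.
#'
#' @param scores_a,scores_b numeric score vectors on identical cases.
#' @param labels class labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p`, `var_diff`, and `degenerate`
#'   (TRUE when the difference has zero estimated variance: `p = 1` if the
#'   AUCs are equal, else `p = 0`).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  y <- as_binary_label(labels)
  m <- sum(y == 1); n <- sum(y == 0)
  if (m < 2 || n < 2) stop("need at least 2 cases per class")
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_diff <= 1e-14) {
    diff <- ca$auc - cb$auc
    # identical scores: no difference, p = 1; a nonzero difference with zero
    # estimated variance is infinitely significant
    return(list(auc_a = ca$auc, auc_b = cb$auc,
                z = if (abs(diff) < 1e-14) 0 else sign(diff) * Inf,
                p = if (abs(diff) < 1e-14) 1 else 0,
                var_diff = var_diff, degenerate = TRUE))
  }
  z <- (ca$auc - cb$auc) / sqrt(var_diff)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), var_diff = var_diff, degenerate = FALSE)
}

# Variance of a single AUC from DeLong components (used for reporting and
# cross-checks).
delong_auc_variance <- function(scores, labels) {
  y <- as_binary_label(labels)
  comp <- delong_components(scores, y)
  stats::var(comp$v10) / sum(y == 1) + stats::var(comp$v01) / sum(y == 0)
}

#' Classification metrics at a decision threshold
#'
#' Cases with score >= threshold are called malignant. Reports sensitivity,
#' specificity, per-class precision and F1, the confusion matrix, and the
#' Mann-Whitney AUC.
#'
#' @param scores numeric malignancy scores.
#' @param labels class labels.
#' @param threshold decision threshold (default 0.5).
#' @return list of metrics.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_label(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec_mal <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  prec_ben <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- function(p, r) if (is.na(p) || is.na(r) || p + r == 0) 0 else 2 * p * r / (p + r)
  list(threshold = threshold,
       confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                          dimnames = list(pred = c("benign", "malignant"),
                                          truth = c("benign", "malignant"))),
       sensitivity = sens, specificity = spec,
       precision_malignant = prec_mal, precision_benign = prec_ben,
       f1_malignant = f1(prec_mal, sens), f1_benign = f1(prec_ben, spec),
       auc = auc_mann_whitney(scores, labels))
}

#' Paired comparison of two binary prediction vectors
#'
#' McNemar's test (continuity-corrected) on the discordant pairs of
#' correct/incorrect calls, and a chi-squared test on the 2x2
#' correct/incorrect contingency table.
#'
#' @param preds_a,preds_b binary (0/1) predictions on identical cases.
#' @param labels class labels.
#' @return list with both statistics and p values; `degenerate` flags zero
#'   discordant pairs (McNemar p = 1).
#' @export
paired_tests <- function(preds_a, preds_b, labels) {
  stopifnot(length(preds_a) == length(preds_b))
  y <- as_binary_label(labels)
  ok_a <- as.integer(preds_a == y); ok_b <- as.integer(preds_b == y)
  b <- sum(ok_a == 1 & ok_b == 0); c_ <- sum(ok_a == 0 & ok_b == 1)
  if (b + c_ == 0) {
    mc_stat <- 0; mc_p <- 1; degen <- TRUE
  } else {
    tb <- table(factor(ok_a, 0:1), factor(ok_b, 0:1))
    mc <- stats::mcnemar.test(tb, correct = TRUE)
    mc_stat <- unname(mc$statistic); mc_p <- mc$p.value; degen <- FALSE
  }
  chi <- suppressWarnings(
    stats::chisq.test(matrix(c(sum(ok_a), length(y) - sum(ok_a),
                               sum(ok_b), length(y) - sum(ok_b)), 2, 2)))
  list(mcnemar_statistic = mc_stat, mcnemar_p = mc_p,
       chisq_statistic = unname(chi$statistic), chisq_p = chi$p.value,
       discordant = c(b = b, c = c_), degenerate = degen)
}

#' Sweep the decision threshold
#'
#' Computes sensitivity, specificity, per-class precision and F1 over a
#' threshold grid, and selects an operating point: the largest grid threshold
#' (at most `max_threshold`) whose sensitivity still meets `sens_target` —
#' i.e. the result of lowering the standard threshold until the sensitivity
#' target is reached.
#'
#' @param scores numeric malignancy scores.
#' @param labels class labels.
#' @param grid threshold grid (default 0 to 1 by 0.01).
#' @param sens_target sensitivity target for the operating point (default 1).
#' @param max_threshold highest admissible operating threshold (default 0.5).
#' @return list with `sweep` (data frame) and `operating_point` (row of the
#'   sweep, or `NULL` if no grid threshold meets the target).
#' @export
threshold_sweep <- function(scores, labels, grid = seq(0, 1, by = 0.01),
                            sens_target = 1, max_threshold = 0.5) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("need both classes for a threshold sweep")
  rows <- lapply(grid, function(t) {
    m <- evaluate_scores(scores, labels, t)
    data.frame(threshold = t, sensitivity = m$sensitivity,
               specificity = m$specificity,
               precision_malignant = m$precision_malignant,
               precision_benign = m$precision_benign,
               f1_malignant = m$f1_malignant, f1_benign = m$f1_benign)
  })
  sw <- do.call(rbind, rows)
  ok <- which(sw$sensitivity >= sens_target & sw$threshold <= max_threshold)
  op <- if (length(ok)) sw[max(ok), , drop = FALSE] else NULL
  list(sweep = sw, operating_point = op)
}
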