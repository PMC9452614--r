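# Parametric empirical-Bayes batch harmonisation (location/scale model
# x = alpha + gamma_batch + delta_batch * eps), fitted per feature with EB
# shrinkage of the per-batch location and scale toward feature-wide priors.

feature_columns <- function(table) {
  setdiff(colnames(table), c("case_id", "batch", "label", "fold"))
}

#' Fit a ComBat harmonisation model to a feature table
#'
#' Per feature f: standardise `z = (x - alpha_f) / sigma_f` (grand mean;
#' pooled scale from residuals around batch means); per batch i take the raw
#' location `gamma_hat[i,f]` (batch mean of z) and scale `delta_hat2[i,f]`
#' (batch variance of z); estimate method-of-moments priors — normal
#' (gamma_bar_i, tau2_i) across features for the locations, inverse-gamma
#' (lambda_i, theta_i) from the empirical mean/variance of the delta_hat2 —
#' and iterate the standard EB fixed-point updates for the shrunken
#' `gamma_star`, `delta_star2` until the largest absolute change falls below
#' `tol` (capped at `max_iter`).
#'
#' With a single batch the model is the identity transform.
#'
#' When `protect` names a column (typically `"label"`), its levels enter the
#' standardisation design matrix so that the batch location/scale estimates
#' are adjusted for it — this keeps biological signal out of the batch-effect
#' estimates when class and batch are correlated. The protected column is
#' used only at fit time; applying the model never reads it, so held-out
#' data can be transformed without their labels. Protection does leak the
#' training labels into the learned transform, hence it is off by default.
#'
#' @param table feature table (columns `case_id`, `batch`, `label` plus
#'   numeric features).
#' @param batch_column name of the batch column (default `"batch"`).
#' @param protect optional name of a categorical column (e.g. `"label"`)
#'   whose effect is protected during estimation.
#' @param tol fixed-point convergence tolerance (default 1e-4).
#' @param max_iter iteration cap (default 100).
#' @return object of class `combat_model`.
#' @export
combat_fit <- function(table, batch_column = "batch", protect = NULL,
                       tol = 1e-4, max_iter = 100L) {
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  batch <- as.character(table[[batch_column]])
  levels_b <- sort(unique(batch))
  nb <- length(levels_b)
  n <- nrow(X)
  if (nb == 1L) {
    mod <- list(batch_column = batch_column, features = feats,
                batch_levels = levels_b, identity = TRUE,
                alpha = colMeans(X), sigma = rep(1, ncol(X)),
                gamma_star = matrix(0, 1, ncol(X)),
                delta_star2 = matrix(1, 1, ncol(X)),
                n_iter = 0L)
    return(structure(mod, class = "combat_model"))
  }
  ni <- table(factor(batch, levels = levels_b))
  if (any(ni < 2)) stop("every batch needs at least 2 cases; too small: ",
                        paste(levels_b[ni < 2], collapse = ", "))
  # design: batch dummies (cell means) plus optional protected covariate
  D <- stats::model.matrix(~ 0 + factor(batch, levels = levels_b))
  if (!is.null(protect)) {
    cov_f <- factor(as.character(table[[protect]]))
    if (nlevels(cov_f) > 1)
      D <- cbind(D, stats::model.matrix(~ cov_f)[, -1, drop = FALSE])
  }
  B <- solve(crossprod(D), crossprod(D, X))
  # grand mean weighted by batch size; pooled variance of residuals around
  # the fitted model (divisor n)
  alpha <- as.vector((ni / n) %*% B[seq_len(nb), , drop = FALSE])
  resid <- X - D %*% B
  sigma2 <- colMeans(resid^2)
  if (any(sigma2 <= 0))
    stop("zero pooled variance for feature(s): ",
         paste(feats[sigma2 <= 0], collapse = ", "))
  sigma <- sqrt(sigma2)
  # standardise the data with the protected-covariate effect removed, so the
  # batch estimates below are not contaminated by it
  X_nocov <- resid + D[, seq_len(nb), drop = FALSE] %*%
    B[seq_len(nb), , drop = FALSE]
  Z <- sweep(sweep(X_nocov, 2, alpha), 2, sigma, `/`)
  gamma_hat <- apply(Z, 2, function(col) tapply(col, batch, mean))
  delta_hat2 <- apply(Z, 2, function(col) tapply(col, batch, stats::var))
  gamma_hat <- matrix(gamma_hat, nb, ncol(X))
  delta_hat2 <- matrix(delta_hat2, nb, ncol(X))

  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  # inverse-gamma hyperparameters by moment matching on delta_hat2
  m_d <- rowMeans(delta_hat2)
  s2_d <- apply(delta_hat2, 1, stats::var)
  lambda <- (2 * s2_d + m_d^2) / s2_d
  theta <- (m_d * s2_d + m_d^3) / s2_d

  gamma_star <- gamma_hat
  delta_star2 <- delta_hat2
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    g_new <- gamma_star; d_new <- delta_star2
    for (i in seq_len(nb)) {
      ssq <- colSums(sweep(Z[batch == levels_b[i], , drop = FALSE], 2,
                           gamma_star[i, ])^2)
      g_new[i, ] <- (ni[i] * tau2[i] * gamma_hat[i, ] +
                       delta_star2[i, ] * gamma_bar[i]) /
        (ni[i] * tau2[i] + delta_star2[i, ])
      d_new[i, ] <- (theta[i] + 0.5 * ssq) / (ni[i] / 2 + lambda[i] - 1)
    }
    delta_move <- max(abs(g_new - gamma_star), abs(d_new - delta_star2))
    gamma_star <- g_new; delta_star2 <- d_new
    n_iter <- it
    if (delta_move < tol) break
  }
  if (any(delta_star2 <= 0)) stop("non-positive shrunken scale; degenerate fit")
  structure(list(batch_column = batch_column, features = feats,
                 batch_levels = levels_b, identity = FALSE,
                 alpha = alpha, sigma = sigma,
                 gamma_hat = gamma_hat, delta_hat2 = delta_hat2,
                 gamma_bar = gamma_bar, tau2 = tau2,
                 lambda = lambda, theta = theta,
                 gamma_star = gamma_star, delta_star2 = delta_star2,
                 n_iter = n_iter),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat("ComBat model:", length(x$features), "features,",
      length(x$batch_levels), "batch level(s)")
  if (x$identity) cat(" (single batch: identity transform)")
  else cat(";", x$n_iter, "EB iterations")
  cat("\n")
  invisible(x)
}

#' Apply a fitted ComBat model to a feature table
#'
#' `x_star = sigma_f * (z - gamma_star[i,f]) / sqrt(delta_star2[i,f]) +
#' alpha_f`. Non-feature columns pass through untouched. Batch labels absent
#' from the fit are an error (no silent extrapolation).
#'
#' @param model a `combat_model`.
#' @param table feature table with the same feature columns.
#' @return harmonised feature table.
#' @export
combat_apply <- function(model, table) {
  stopifnot(inherits(model, "combat_model"))
  feats <- model$features
  missing_f <- setdiff(feats, colnames(table))
  if (length(missing_f)) stop("table lacks fitted features: ",
                              paste(utils::head(missing_f, 3), collapse = ", "))
  if (model$identity) return(table)
  batch <- as.character(table[[model$batch_column]])
  unseen <- setdiff(unique(batch), model$batch_levels)
  if (length(unseen)) stop("unseen batch label(s): ",
                           paste(unseen, collapse = ", "))
  X <- as.matrix(table[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  Z <- sweep(sweep(X, 2, model$alpha), 2, model$sigma, `/`)
  bi <- match(batch, model$batch_levels)
  Zc <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star2)[bi, , drop = FALSE]
  Xc <- sweep(sweep(Zc, 2, model$sigma, `*`), 2, model$alpha, `+`)
  out <- table
  out[, feats] <- Xc
  out
}

#' Fit and apply ComBat in one step
#'
#' @inheritParams combat_fit
#' @return harmonised feature table.
#' @export
combat_harmonize <- function(table, batch_column = "batch", ...) {
  combat_apply(combat_fit(table, batch_column, ...), table)
}
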