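# A small convolutional network for tumour-slice classification, written in
# base R (im2col convolutions via BLAS matrix products). Topology: three
# blocks of [3x3 conv -> batch-norm -> ReLU -> 2x2 max-pool -> dropout],
# then flatten -> dense(32, ReLU) -> dropout -> dense(1, sigmoid). Trained
# with Adam on class-weighted binary cross-entropy; intended for CPU-scale
# phantom experiments, not GPU workloads.

#' Build the slice-classification CNN
#'
#' @param input_size square input size in pixels (default 224).
#' @param widths convolution channel widths of the three blocks.
#' @param dense_units units of the fully connected layer (default 32).
#' @param dropout dropout rates: one per block plus one before the output
#'   layer.
#' @param seed integer seed for weight initialisation (He-style).
#' @return object of class `liporad_cnn`.
#' @export
build_cnn <- function(input_size = 224, widths = c(8, 16, 32),
                      dense_units = 32, dropout = c(0.25, 0.25, 0.25, 0.5),
                      seed = 1L) {
  stopifnot(length(widths) == 3, length(dropout) == 4)
  sizes <- input_size
  for (i in 1:3) sizes <- c(sizes, sizes[length(sizes)] %/% 2L)
  if (sizes[4] < 1) stop("input_size too small for three pooling stages")
  flat <- sizes[4]^2 * widths[3]
  layers <- list()
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (b in 1:3) {
      fan_in <- 9L * cin
      p[[paste0("conv", b, "_W")]] <-
        matrix(stats::rnorm(fan_in * widths[b], sd = sqrt(2 / fan_in)),
               fan_in, widths[b])
      p[[paste0("conv", b, "_b")]] <- rep(0, widths[b])
      p[[paste0("bn", b, "_gamma")]] <- rep(1, widths[b])
      p[[paste0("bn", b, "_beta")]] <- rep(0, widths[b])
      cin <- widths[b]
    }
    p[["dense1_W"]] <- matrix(stats::rnorm(dense_units * flat,
                                           sd = sqrt(2 / flat)),
                              dense_units, flat)
    p[["dense1_b"]] <- rep(0, dense_units)
    p[["dense2_W"]] <- matrix(stats::rnorm(dense_units, sd = sqrt(1 / dense_units)),
                              1, dense_units)
    p[["dense2_b"]] <- 0
    p
  })
  for (b in 1:3) {
    layers <- c(layers, list(
      list(type = "conv", block = b),
      list(type = "batchnorm", block = b),
      list(type = "relu"),
      list(type = "maxpool"),
      list(type = "dropout", p = dropout[b])))
  }
  layers <- c(layers, list(list(type = "flatten"),
                           list(type = "dense", id = 1),
                           list(type = "relu"),
                           list(type = "dropout", p = dropout[4]),
                           list(type = "dense", id = 2),
                           list(type = "sigmoid")))
  structure(list(input_size = input_size, widths = widths,
                 dense_units = dense_units, dropout = dropout,
                 layers = layers, params = params,
                 running = list(bn1_mean = rep(0, widths[1]),
                                bn1_var = rep(1, widths[1]),
                                bn2_mean = rep(0, widths[2]),
                                bn2_var = rep(1, widths[2]),
                                bn3_mean = rep(0, widths[3]),
                                bn3_var = rep(1, widths[3])),
                 seed = seed),
            class = "liporad_cnn")
}

#' @export
print.liporad_cnn <- function(x, ...) {
  cat("CNN:", x$input_size, "x", x$input_size, "input ->",
      paste(sapply(x$layers, function(l) l$type), collapse = " -> "), "\n")
  cat("widths", paste(x$widths, collapse = "/"),
      "; dense", x$dense_units, "; dropout",
      paste(x$dropout, collapse = "/"), "\n")
  invisible(x)
}

# im2col for 3x3 same-padding convolution. X: matrix (H*W*N) x C (column
# major over H, then W, then N). Returns (H*W*N) x (9*C).
im2col3 <- function(X, H, W, N) {
  C <- ncol(X)
  P <- array(0, c(H + 2L, W + 2L, N, C))
  P[2:(H + 1L), 2:(W + 1L), , ] <- array(X, c(H, W, N, C))
  out <- matrix(0, H * W * N, 9L * C)
  col <- 0L
  for (c_ in seq_len(C)) for (kj in 1:3) for (ki in 1:3) {
    col <- col + 1L
    out[, col] <- P[ki:(ki + H - 1L), kj:(kj + W - 1L), , c_]
  }
  out
}

col2im3 <- function(dcol, H, W, N, C) {
  dP <- array(0, c(H + 2L, W + 2L, N, C))
  col <- 0L
  for (c_ in seq_len(C)) for (kj in 1:3) for (ki in 1:3) {
    col <- col + 1L
    dP[ki:(ki + H - 1L), kj:(kj + W - 1L), , c_] <-
      dP[ki:(ki + H - 1L), kj:(kj + W - 1L), , c_] +
      array(dcol[, col], c(H, W, N))
  }
  matrix(dP[2:(H + 1L), 2:(W + 1L), , , drop = FALSE], H * W * N, C)
}

cnn_forward <- function(model, X, train = FALSE, update_running = train) {
  # X: array (H, W, N)
  d <- dim(X)
  H <- d[1]; W <- d[2]; N <- d[3]
  A <- matrix(as.numeric(X), H * W * N, 1L)
  cache <- list()
  eps <- 1e-5
  running <- model$running
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    cc <- list(type = l$type, H = H, W = W, N = N)
    if (l$type == "conv") {
      Wm <- model$params[[paste0("conv", l$block, "_W")]]
      bb <- model$params[[paste0("conv", l$block, "_b")]]
      Xc <- im2col3(A, H, W, N)
      A <- sweep(Xc %*% Wm, 2, bb, `+`)
      cc$Xc <- Xc; cc$Cin <- nrow(Wm) %/% 9L; cc$block <- l$block
    } else if (l$type == "batchnorm") {
      g <- model$params[[paste0("bn", l$block, "_gamma")]]
      be <- model$params[[paste0("bn", l$block, "_beta")]]
      if (train) {
        mu <- colMeans(A)
        v <- colMeans(sweep(A, 2, mu)^2)
        if (update_running) {
          running[[paste0("bn", l$block, "_mean")]] <-
            0.9 * running[[paste0("bn", l$block, "_mean")]] + 0.1 * mu
          running[[paste0("bn", l$block, "_var")]] <-
            0.9 * running[[paste0("bn", l$block, "_var")]] + 0.1 * v
        }
      } else {
        mu <- running[[paste0("bn", l$block, "_mean")]]
        v <- running[[paste0("bn", l$block, "_var")]]
      }
      xhat <- sweep(sweep(A, 2, mu), 2, sqrt(v + eps), `/`)
      cc$xhat <- xhat; cc$mu <- mu; cc$v <- v; cc$block <- l$block
      cc$train <- train
      A <- sweep(sweep(xhat, 2, g, `*`), 2, be, `+`)
    } else if (l$type == "relu") {
      cc$mask <- A > 0
      A <- A * cc$mask
    } else if (l$type == "maxpool") {
      H2 <- H %/% 2L; W2 <- W %/% 2L
      F_ <- ncol(A)
      arr <- array(A, c(H, W, N, F_))
      io <- seq_len(H2) * 2L - 1L; jo <- seq_len(W2) * 2L - 1L
      a11 <- arr[io, jo, , , drop = FALSE]
      a21 <- arr[io + 1L, jo, , , drop = FALSE]
      a12 <- arr[io, jo + 1L, , , drop = FALSE]
      a22 <- arr[io + 1L, jo + 1L, , , drop = FALSE]
      M <- pmax(a11, a21, a12, a22)
      m1 <- a11 == M; m2 <- a21 == M & !m1
      m3 <- a12 == M & !m1 & !m2; m4 <- !(m1 | m2 | m3)
      cc$masks <- list(m1, m2, m3, m4); cc$H2 <- H2; cc$W2 <- W2; cc$F <- F_
      A <- matrix(M, H2 * W2 * N, F_)
      H <- H2; W <- W2
    } else if (l$type == "dropout") {
      if (train && l$p > 0) {
        keep <- (matrix(stats::runif(length(A)), nrow(A)) >= l$p) / (1 - l$p)
        cc$keep <- keep
        A <- A * keep
      }
    } else if (l$type == "flatten") {
      F_ <- ncol(A)
      arr <- aperm(array(A, c(H, W, N, F_)), c(1, 2, 4, 3))
      cc$F <- F_
      A <- matrix(arr, H * W * F_, N)   # (flat) x N
    } else if (l$type == "dense") {
      Wm <- model$params[[paste0("dense", l$id, "_W")]]
      bb <- model$params[[paste0("dense", l$id, "_b")]]
      cc$input <- A; cc$id <- l$id
      A <- Wm %*% A + bb
    } else if (l$type == "sigmoid") {
      A <- 1 / (1 + exp(-A))
      cc$out <- A
    }
    cache[[li]] <- cc
  }
  list(prob = as.numeric(A), cache = cache, running = running)
}

cnn_backward <- function(model, fwd, y, w) {
  # gradient of weighted BCE wrt all params; w normalised internally
  cache <- fwd$cache
  p <- fwd$prob
  wn <- w / sum(w)
  grads <- list()
  # d(loss)/d(logit) for sigmoid + BCE
  dA <- matrix(wn * (p - y), 1)
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cc <- cache[[li]]
    if (l$type == "sigmoid") {
      # folded into the logit gradient above
    } else if (l$type == "dense") {
      Wm <- model$params[[paste0("dense", l$id, "_W")]]
      grads[[paste0("dense", l$id, "_W")]] <- dA %*% t(cc$input)
      grads[[paste0("dense", l$id, "_b")]] <- rowSums(dA)
      dA <- t(Wm) %*% dA
    } else if (l$type == "flatten") {
      H <- cc$H; W <- cc$W; N <- cc$N; F_ <- cc$F
      arr <- aperm(array(dA, c(H, W, F_, N)), c(1, 2, 4, 3))
      dA <- matrix(arr, H * W * N, F_)
    } else if (l$type == "dropout") {
      if (!is.null(cc$keep)) dA <- dA * cc$keep
    } else if (l$type == "maxpool") {
      H2 <- cc$H2; W2 <- cc$W2; N <- cc$N; F_ <- cc$F
      H <- cc$H; W <- cc$W
      dM <- array(dA, c(H2, W2, N, F_))
      darr <- array(0, c(H, W, N, F_))
      io <- seq_len(H2) * 2L - 1L; jo <- seq_len(W2) * 2L - 1L
      ms <- cc$masks
      darr[io, jo, , ] <- dM * ms[[1]]
      darr[io + 1L, jo, , ] <- dM * ms[[2]]
      darr[io, jo + 1L, , ] <- dM * ms[[3]]
      darr[io + 1L, jo + 1L, , ] <- dM * ms[[4]]
      dA <- matrix(darr, H * W * N, F_)
    } else if (l$type == "relu") {
      dA <- dA * cc$mask
    } else if (l$type == "batchnorm") {
      g <- model$params[[paste0("bn", cc$block, "_gamma")]]
      eps <- 1e-5
      xhat <- cc$xhat
      m <- nrow(xhat)
      grads[[paste0("bn", cc$block, "_gamma")]] <- colSums(dA * xhat)
      grads[[paste0("bn", cc$block, "_beta")]] <- colSums(dA)
      if (isTRUE(cc$train)) {
        dxhat <- sweep(dA, 2, g, `*`)
        inv_sd <- 1 / sqrt(cc$v + eps)
        t1 <- sweep(dxhat, 2, colMeans(dxhat))
        t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
        dA <- sweep(t1 - t2, 2, inv_sd, `*`)
      } else {
        dA <- sweep(sweep(dA, 2, g, `*`), 2, sqrt(cc$v + eps), `/`)
      }
    } else if (l$type == "conv") {
      Wm <- model$params[[paste0("conv", cc$block, "_W")]]
      grads[[paste0("conv", cc$block, "_W")]] <- t(cc$Xc) %*% dA
      grads[[paste0("conv", cc$block, "_b")]] <- colSums(dA)
      dcol <- dA %*% t(Wm)
      dA <- col2im3(dcol, cc$H, cc$W, cc$N, cc$Cin)
    }
  }
  grads
}

cnn_loss <- function(prob, y, w) {
  wn <- w / sum(w)
  eps <- 1e-12
  -sum(wn * (y * log(prob + eps) + (1 - y) * log(1 - prob + eps)))
}

#' Randomly augment a slice image
#'
#' Horizontal/vertical flips (probability 1/2 each), zoom within
#' `1 +/- zoom`, rotation within `+/- rotate` degrees, and translation within
#' `+/- shift` of the image size, sampled bilinearly with edge replication.
#' Deterministic given the seed; with all ranges 0 and flips disabled, the
#' image is returned unchanged.
#'
#' @param image square numeric matrix.
#' @param seed integer seed.
#' @param flip allow flips.
#' @param zoom,rotate,shift augmentation ranges (fraction, degrees, fraction).
#' @return augmented image of identical shape.
#' @export
augment_slice <- function(image, seed, flip = TRUE, zoom = 0.1, rotate = 15,
                          shift = 0.1) {
  d <- dim(image)
  with_seed(seed, {
    if (flip && stats::runif(1) < 0.5) image <- image[d[1]:1, , drop = FALSE]
    if (flip && stats::runif(1) < 0.5) image <- image[, d[2]:1, drop = FALSE]
    ang <- stats::runif(1, -rotate, rotate) * pi / 180
    zf <- 1 + stats::runif(1, -zoom, zoom)
    dx <- stats::runif(1, -shift, shift) * d[1]
    dy <- stats::runif(1, -shift, shift) * d[2]
    if (ang == 0 && zf == 1 && dx == 0 && dy == 0) return(image)
    cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
    ox <- matrix(seq_len(d[1]), d[1], d[2]) - cx
    oy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cy
    xs <- cx + (cos(ang) * ox - sin(ang) * oy) / zf - dx
    ys <- cy + (sin(ang) * ox + cos(ang) * oy) / zf - dy
    bilinear_sample(image, xs, ys)
  })
}

#' Predict slice probabilities with a trained CNN
#'
#' @param object a `liporad_cnn`.
#' @param newdata array (H, W, n_slices) of z-scored slices.
#' @param ... unused.
#' @return numeric vector of malignancy probabilities.
#' @export
predict.liporad_cnn <- function(object, newdata, ...) {
  if (length(dim(newdata)) == 2L) dim(newdata) <- c(dim(newdata), 1L)
  cnn_forward(object, newdata, train = FALSE)$prob
}

#' Fit the CNN on a slice set
#'
#' Adam optimisation of class-weighted binary cross-entropy (weights inverse
#' to slice-class frequency), optional augmentation, optional early stopping
#' on a validation slice set.
#'
#' @param model a `liporad_cnn`.
#' @param X array (H, W, n_slices) of z-scored slices.
#' @param y numeric 0/1 labels per slice.
#' @param epochs maximum epochs (default 50).
#' @param batch_size minibatch size (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param augment apply [augment_slice()] to each training slice per epoch.
#' @param val optional list(X, y) for early stopping.
#' @param patience early-stopping patience in epochs (default 10).
#' @param seed integer seed (shuffling, dropout, augmentation).
#' @param verbose print per-epoch loss.
#' @return the trained model (with `history` attached).
#' @export
cnn_fit <- function(model, X, y, epochs = 50, batch_size = 16, lr = 1e-3,
                    augment = FALSE, val = NULL, patience = 10, seed = 1L,
                    verbose = FALSE) {
  n <- dim(X)[3]
  stopifnot(length(y) == n)
  # class weights inverse to slice-class frequency
  w <- ifelse(y == 1, n / (2 * max(sum(y == 1), 1)),
              n / (2 * max(sum(y == 0), 1)))
  mstate <- lapply(model$params, function(p) p * 0)
  vstate <- mstate
  t_ <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf; best_params <- model$params; best_running <- model$running
  wait <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (s in seq(1L, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        if (length(idx) < 2L) next   # batch-norm needs > 1 sample
        Xb <- X[, , idx, drop = FALSE]
        if (augment) {
          for (q in seq_along(idx))
            Xb[, , q] <- augment_slice(Xb[, , q],
                                       seed = floor(stats::runif(1, 0, 2^30)))
        }
        fwd <- cnn_forward(model, Xb, train = TRUE)
        model$running <- fwd$running
        gr <- cnn_backward(model, fwd, y[idx], w[idx])
        ep_loss <- ep_loss + cnn_loss(fwd$prob, y[idx], w[idx]); nb <- nb + 1
        t_ <- t_ + 1
        for (pn in names(gr)) {
          mstate[[pn]] <- b1 * mstate[[pn]] + (1 - b1) * gr[[pn]]
          vstate[[pn]] <- b2 * vstate[[pn]] + (1 - b2) * gr[[pn]]^2
          mhat <- mstate[[pn]] / (1 - b1^t_)
          vhat <- vstate[[pn]] / (1 - b2^t_)
          model$params[[pn]] <- model$params[[pn]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      vl <- NA_real_
      if (!is.null(val)) {
        pv <- cnn_forward(model, val$X, train = FALSE)$prob
        wv <- rep(1, length(val$y))
        vl <- cnn_loss(pv, val$y, wv)
        if (vl < best_val - 1e-6) {
          best_val <- vl; best_params <- model$params
          best_running <- model$running; wait <- 0
        } else wait <- wait + 1
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = ep_loss / max(nb, 1),
                                  val_loss = vl))
      if (verbose) message(sprintf("epoch %d loss %.4f val %.4f", ep,
                                   ep_loss / max(nb, 1), vl))
      if (!is.null(val) && wait >= patience) break
    }
  })
  if (!is.null(val)) {
    model$params <- best_params
    model$running <- best_running
  }
  model$history <- history
  model
}

#' Build the slice dataset for the CNN arm
#'
#' Crops and resizes every mask-bearing slice of each case and z-scores each
#' slice individually (constant slices are dropped).
#'
#' @param manifest cohort manifest (case_id, batch, label, image, mask).
#' @param out_size slice size (default 224).
#' @return list with `X` (array out_size x out_size x n_slices), `case_id`,
#'   `label` (character), `y` (0/1 per slice).
#' @export
build_slice_dataset <- function(manifest, out_size = 224) {
  Xs <- list(); cid <- character(0); lab <- character(0)
  for (r in seq_len(nrow(manifest))) {
    v <- read_case(manifest$image[r], manifest$mask[r],
                   case_id = manifest$case_id[r], label = manifest$label[r])
    sl <- crop_and_resize_slices(v, out_size = out_size)
    for (s in seq_len(dim(sl$slices)[3])) {
      img <- sl$slices[, , s]
      if (stats::sd(img) <= 0) next
      Xs[[length(Xs) + 1L]] <- zscore_normalize(img)
      cid <- c(cid, manifest$case_id[r])
      lab <- c(lab, manifest$label[r])
    }
  }
  X <- array(0, c(out_size, out_size, length(Xs)))
  for (s in seq_along(Xs)) X[, , s] <- Xs[[s]]
  list(X = X, case_id = cid, label = lab, y = as_binary_label(lab))
}

#' Cross-validated CNN scores at case level
#'
#' Trains one CNN per fold on all slices of the training cases and scores
#' the held-out cases; a case's score is the mean probability of its slices.
#' Slices never straddle folds because folding is by case.
#'
#' @param dataset from [build_slice_dataset()].
#' @param plan a [make_cv_plan()] over the same cases.
#' @param epochs,batch_size,lr,augment,seed training controls.
#' @param widths,dense_units,dropout passed to [build_cnn()].
#' @param verbose print progress.
#' @return data frame case_id, label, fold, score.
#' @export
cnn_cross_validate <- function(dataset, plan, epochs = 30, batch_size = 16,
                               lr = 1e-3, augment = FALSE, seed = 1L,
                               widths = c(8, 16, 32), dense_units = 32,
                               dropout = c(0.25, 0.25, 0.25, 0.5),
                               verbose = FALSE) {
  stopifnot(inherits(plan, "cv_plan"))
  fold <- plan$fold[dataset$case_id]
  if (anyNA(fold)) stop("plan does not cover all slice cases")
  out <- list()
  input_size <- dim(dataset$X)[1]
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    if (length(unique(dataset$y[tr])) < 2)
      stop("training fold ", f, " lacks both classes")
    model <- build_cnn(input_size, widths = widths, dense_units = dense_units,
                       dropout = dropout, seed = derive_seed(seed, f))
    model <- cnn_fit(model, dataset$X[, , tr, drop = FALSE], dataset$y[tr],
                     epochs = epochs, batch_size = batch_size, lr = lr,
                     augment = augment, seed = derive_seed(seed, 100L + f),
                     verbose = verbose)
    pr <- predict(model, dataset$X[, , te, drop = FALSE])
    agg <- tapply(pr, dataset$case_id[te], mean)
    lab <- tapply(dataset$label[te], dataset$case_id[te], `[`, 1)
    out[[length(out) + 1L]] <- data.frame(case_id = names(agg),
                                          label = as.character(lab),
                                          fold = f, score = as.numeric(agg),
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
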