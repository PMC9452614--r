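# Internal numeric helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a per-case sub-seed that stays inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve every column of a matrix with kernel k, edge-replicated rows.
conv_cols_replicate <- function(m, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  mp <- rbind(m[rep(1L, half), , drop = FALSE], m,
              m[rep(n, half), , drop = FALSE])
  f <- stats::filter(mp, k, sides = 2)
  matrix(as.numeric(f), nrow(mp))[(half + 1L):(half + n), , drop = FALSE]
}

# Separable 3D Gaussian blur, edge-replicated. Used for correlated noise and
# for the per-batch acquisition blur.
gaussian_blur_3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gaussian_kernel_1d(sigma)
  if (length(k) == 1L) return(a)
  d <- dim(a)
  blur1 <- function(x) {
    dx <- dim(x)
    array(conv_cols_replicate(matrix(x, dx[1]), k), dx)
  }
  out <- blur1(a)
  out <- aperm(blur1(aperm(out, c(2, 1, 3))), c(2, 1, 3))
  out <- aperm(blur1(aperm(out, c(3, 2, 1))), c(3, 2, 1))
  out
}

# 2D convolution (correlation) of image with kernel, replicate-padded, output
# the size of the image. FFT-based so kernels larger than the image are fine.
conv2d_replicate <- function(img, kernel) {
  di <- dim(img); dk <- dim(kernel)
  hi <- (dk[1] - 1L) %/% 2L; hj <- (dk[2] - 1L) %/% 2L
  ri <- pmin(pmax(seq_len(di[1] + 2L * hi) - hi, 1L), di[1])
  rj <- pmin(pmax(seq_len(di[2] + 2L * hj) - hj, 1L), di[2])
  pad <- img[ri, rj, drop = FALSE]
  dp <- dim(pad)
  kf <- matrix(0, dp[1], dp[2])
  kf[seq_len(dk[1]), seq_len(dk[2])] <- kernel[dk[1]:1, dk[2]:1, drop = FALSE]
  full <- Re(stats::fft(stats::fft(pad) * stats::fft(kf), inverse = TRUE)) / prod(dp)
  # 'full' index (i, j) holds sum over kernel of pad[i - u, j - v]; the sample
  # aligned with pad position (i, j) and a centred kernel sits at (i + hi, j + hj).
  full[(2L * hi + 1L):(2L * hi + di[1]), (2L * hj + 1L):(2L * hj + di[2]), drop = FALSE]
}

# Bilinear sampling of a 2D image at (possibly fractional) coordinates, with
# coordinate clamping (edge replication). xs/ys are matrices of row/col coords.
bilinear_sample <- function(img, xs, ys) {
  d <- dim(img)
  xs <- pmin(pmax(xs, 1), d[1]); ys <- pmin(pmax(ys, 1), d[2])
  x0 <- pmin(floor(xs), d[1] - 1L); y0 <- pmin(floor(ys), d[2] - 1L)
  if (d[1] == 1L) x0[] <- 1L
  if (d[2] == 1L) y0[] <- 1L
  fx <- xs - x0; fy <- ys - y0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2])
  i00 <- cbind(as.vector(x0), as.vector(y0)); i10 <- cbind(as.vector(x1), as.vector(y0))
  i01 <- cbind(as.vector(x0), as.vector(y1)); i11 <- cbind(as.vector(x1), as.vector(y1))
  v <- img[i00] * as.vector((1 - fx) * (1 - fy)) +
       img[i10] * as.vector(fx * (1 - fy)) +
       img[i01] * as.vector((1 - fx) * fy) +
       img[i11] * as.vector(fx * fy)
  matrix(v, nrow(xs), ncol(xs))
}

# Resize a 2D image to out_rows x out_cols by bilinear interpolation.
resize_bilinear <- function(img, out_rows, out_cols) {
  d <- dim(img)
  xs <- matrix(seq(1, d[1], length.out = out_rows), out_rows, out_cols)
  ys <- matrix(seq(1, d[2], length.out = out_cols), out_rows, out_cols, byrow = TRUE)
  bilinear_sample(img, xs, ys)
}

# Bounding box of TRUE entries of a 3D logical array: 3 x 2 matrix (lo, hi).
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  t(apply(idx, 2, range))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
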