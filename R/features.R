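# The fixed 92-feature radiomic catalog and its per-family computations.
# Matrix-family features follow the IBSI formulae; log terms use log2 with
# 0*log(0) = 0; NGTDM uses eps = 1e-12 with coarseness capped at 1e6;
# correlation-type features with zero marginal variance return 1.

GABOR_ORIENTATIONS <- seq(0, 150, by = 30)        # degrees, k*pi/6
GABOR_WAVELENGTHS <- 3 * 2^(seq(0, 2, by = 0.5))  # half-octave ladder from 3

#' The radiomic feature catalog
#'
#' Ordered list of the 92 features: shape (14), histogram (14), GLCM (21),
#' GLRLM (13), GLSZM (13), NGTDM (5), Gabor (12). Names and order are stable
#' across runs; the feature table columns follow this order.
#'
#' @return data frame with columns `name` and `family`.
#' @export
feature_catalog <- function() {
  fam <- function(family, names) data.frame(name = names, family = family,
                                            stringsAsFactors = FALSE)
  cat_ <- rbind(
    fam("shape", paste0("shape_", c(
      "voxel_count", "volume_mm3", "surface_area_mm2", "surface_to_volume",
      "sphericity", "compactness1", "compactness2", "spherical_disproportion",
      "max_diameter_mm", "major_axis_mm", "minor_axis_mm", "least_axis_mm",
      "elongation", "flatness"))),
    fam("histogram", paste0("hist_", c(
      "mean", "variance", "skewness", "kurtosis", "median", "min", "max",
      "range", "p10", "p90", "iqr", "energy", "entropy", "uniformity"))),
    fam("glcm", paste0("glcm_", c(
      "autocorrelation", "cluster_prominence", "cluster_shade", "contrast",
      "correlation", "difference_entropy", "difference_variance",
      "dissimilarity", "energy", "entropy", "idm", "idmn", "id", "idn",
      "imc1", "imc2", "max_probability", "sum_average", "sum_entropy",
      "sum_variance", "variance"))),
    fam("glrlm", paste0("glrlm_", c(
      "sre", "lre", "gln", "rln", "run_percentage", "lgre", "hgre", "srlge",
      "srhge", "lrlge", "lrhge", "glv", "rlv"))),
    fam("glszm", paste0("glszm_", c(
      "sae", "lae", "gln", "szn", "zone_percentage", "lgze", "hgze", "salge",
      "sahge", "lalge", "lahge", "glv", "zv"))),
    fam("ngtdm", paste0("ngtdm_", c(
      "coarseness", "contrast", "busyness", "complexity", "strength"))),
    fam("gabor", c(paste0("gabor_mean_", GABOR_ORIENTATIONS),
                   paste0("gabor_sd_", GABOR_ORIENTATIONS)))
  )
  stopifnot(nrow(cat_) == 92L, !anyDuplicated(cat_$name))
  cat_
}

.onLoad <- function(libname, pkgname) {
  sizes <- table(feature_catalog()$family)
  stopifnot(sizes[["shape"]] == 14L, sizes[["histogram"]] == 14L,
            sizes[["glcm"]] == 21L, sizes[["glrlm"]] == 13L,
            sizes[["glszm"]] == 13L, sizes[["ngtdm"]] == 5L,
            sizes[["gabor"]] == 12L, sum(sizes) == 92L)
}

## ---- shape -----------------------------------------------------------------

# Surface mesh area by marching tetrahedra at iso-level 0.5 on a lightly
# Gaussian-smoothed copy of the binary mask (vertices at voxel centres,
# physical spacing, linear edge interpolation). Smoothing removes the
# voxelisation staircase that would otherwise bias the area upward; the mask
# is zero-padded so lesions touching the array edge yield a closed surface.
TET_DECOMP <- matrix(c(1,2,3,7, 1,3,4,7, 1,4,8,7, 1,8,5,7, 1,5,6,7, 1,6,2,7),
                     nrow = 4)
CUBE_OFFSETS <- matrix(c(0,0,0, 1,0,0, 1,1,0, 0,1,0,
                         0,0,1, 1,0,1, 1,1,1, 0,1,1), nrow = 3)

mesh_surface_area <- function(mask, spacing, smooth_sigma = 0.7) {
  bb <- mask_bbox(mask)
  mask <- mask[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2],
               drop = FALSE]
  d <- dim(mask)
  m <- array(0, d + 4L)
  m[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- as.numeric(mask)
  field <- gaussian_blur_3d(m, smooth_sigma)
  a <- tet_mesh_area(field, spacing, iso = 0.5)
  if (a == 0) a <- tet_mesh_area(m, spacing, iso = 0.5)  # very small lesions
  a
}

tet_mesh_area <- function(field, spacing, iso = 0.5) {
  dm <- dim(field)
  strides <- c(1L, dm[1], dm[1] * dm[2])
  sub <- function(dx, dy, dz) field[(1 + dx):(dm[1] - 1 + dx),
                                    (1 + dy):(dm[2] - 1 + dy),
                                    (1 + dz):(dm[3] - 1 + dz), drop = FALSE]
  lo <- array(Inf, dm - 1L); hi <- array(-Inf, dm - 1L)
  for (c_ in seq_len(8)) {
    s <- sub(CUBE_OFFSETS[1, c_], CUBE_OFFSETS[2, c_], CUBE_OFFSETS[3, c_])
    lo <- pmin(lo, s); hi <- pmax(hi, s)
  }
  cells <- which(lo < iso & hi >= iso)
  if (length(cells) == 0L) return(0)
  base <- arrayInd(cells, dm - 1L)                    # cell corner voxel index
  base_lin <- as.vector((base - 1L) %*% strides) + 1L
  voff <- function(c_) sum(CUBE_OFFSETS[, c_] * strides)
  vcoord <- function(c_) sweep(sweep(base, 2, CUBE_OFFSETS[, c_], `+`), 2,
                               spacing, `*`)
  cross_norm <- function(u, v) {
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    sqrt(cx^2 + cy^2 + cz^2)
  }
  interp <- function(sa, sb, Pa, Pb) {
    t <- (iso - sa) / (sb - sa)
    Pa + t * (Pb - Pa)
  }
  area <- 0
  for (t_ in seq_len(6)) {
    vid <- TET_DECOMP[, t_]
    S <- sapply(vid, function(c_) field[base_lin + voff(c_)])
    if (is.null(dim(S))) S <- matrix(S, nrow = 1)
    P <- lapply(vid, vcoord)
    inside <- S >= iso
    n_in <- rowSums(inside)
    mixed <- which(n_in > 0 & n_in < 4)
    if (length(mixed) == 0L) next
    pid <- as.vector(inside %*% c(1L, 2L, 4L, 8L))
    for (pat in unique(pid[mixed])) {
      b <- as.logical(bitwAnd(pat, c(1L, 2L, 4L, 8L)))
      sel <- mixed[pid[mixed] == pat]
      if (sum(b) %in% c(1L, 3L)) {
        lone <- if (sum(b) == 1L) which(b) else which(!b)
        rest <- setdiff(1:4, lone)
        pts <- lapply(rest, function(k)
          interp(S[sel, lone], S[sel, k],
                 P[[lone]][sel, , drop = FALSE], P[[k]][sel, , drop = FALSE]))
        area <- area + sum(0.5 * cross_norm(pts[[2]] - pts[[1]],
                                            pts[[3]] - pts[[1]]))
      } else {
        ins <- which(b); outs <- which(!b)
        m1 <- interp(S[sel, ins[1]], S[sel, outs[1]],
                     P[[ins[1]]][sel, , drop = FALSE], P[[outs[1]]][sel, , drop = FALSE])
        m2 <- interp(S[sel, ins[1]], S[sel, outs[2]],
                     P[[ins[1]]][sel, , drop = FALSE], P[[outs[2]]][sel, , drop = FALSE])
        m3 <- interp(S[sel, ins[2]], S[sel, outs[2]],
                     P[[ins[2]]][sel, , drop = FALSE], P[[outs[2]]][sel, , drop = FALSE])
        m4 <- interp(S[sel, ins[2]], S[sel, outs[1]],
                     P[[ins[2]]][sel, , drop = FALSE], P[[outs[1]]][sel, , drop = FALSE])
        area <- area + sum(0.5 * cross_norm(m2 - m1, m3 - m1)) +
          sum(0.5 * cross_norm(m3 - m1, m4 - m1))
      }
    }
  }
  area
}

# Largest pairwise distance between boundary voxel centres (physical mm);
# exact for <= `exact_limit` boundary voxels, else computed over extreme
# points of many random projections (convex-hull style approximation).
max_diameter <- function(coords, exact_limit = 5000L) {
  n <- nrow(coords)
  if (n > exact_limit) {
    set <- unique(unlist(lapply(seq_len(200), function(i) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      pr <- coords %*% u
      c(which.min(pr), which.max(pr))
    })))
    coords <- coords[set, , drop = FALSE]
    n <- nrow(coords)
  }
  best <- 0
  chunk <- 512L
  sq <- rowSums(coords^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(coords[s:e, , drop = FALSE], coords)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Shape features from a binary mask
#'
#' Fourteen size/shape descriptors: voxel count, physical volume, mesh
#' surface area, surface-to-volume ratio, sphericity, two compactness
#' variants, spherical disproportion, maximum 3D diameter, and the three
#' principal-axis lengths with elongation and flatness.
#'
#' @param mask 3D logical array (single 26-connected component).
#' @param spacing voxel spacing in mm (length 3).
#' @return named numeric vector of length 14.
#' @export
shape_features <- function(mask, spacing) {
  stopifnot(length(dim(mask)) == 3, length(spacing) == 3)
  nv <- sum(mask)
  if (nv == 0L) stop("empty mask")
  if (!single_component_26(mask))
    stop("mask is not a single 26-connected component")
  V <- nv * prod(spacing)
  A <- mesh_surface_area(mask, spacing)
  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx, 2, spacing, `*`)
  # boundary voxels: at least one 6-neighbour outside the mask
  d <- dim(mask)
  inner <- array(TRUE, d)
  shift_all <- function(msk, ax, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len); dst <- src
    src[[ax]] <- src[[ax]] - by
    keep <- src[[ax]] >= 1 & src[[ax]] <= d[ax]
    dst[[ax]] <- dst[[ax]][keep]; src[[ax]] <- src[[ax]][keep]
    out[dst[[1]], dst[[2]], dst[[3]]] <- msk[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) inner <- inner & shift_all(mask, ax, by)
  boundary <- mask & !inner
  bidx <- which(boundary, arr.ind = TRUE)
  if (nrow(bidx) == 0L) bidx <- idx
  diam <- max_diameter(sweep(bidx, 2, spacing, `*`))
  cv <- stats::cov(coords)
  ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  axes <- 4 * sqrt(ev)
  R_eq <- (3 * V / (4 * pi))^(1 / 3)
  c(shape_voxel_count = nv,
    shape_volume_mm3 = V,
    shape_surface_area_mm2 = A,
    shape_surface_to_volume = A / V,
    shape_sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    shape_compactness1 = V / (sqrt(pi) * A^1.5),
    shape_compactness2 = 36 * pi * V^2 / A^3,
    shape_spherical_disproportion = A / (4 * pi * R_eq^2),
    shape_max_diameter_mm = diam,
    shape_major_axis_mm = axes[1],
    shape_minor_axis_mm = axes[2],
    shape_least_axis_mm = axes[3],
    shape_elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    shape_flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}

## ---- histogram -------------------------------------------------------------

#' Intensity histogram features
#'
#' First-order statistics of masked intensities; entropy and uniformity come
#' from a 256-equal-width-bin histogram over the observed range.
#'
#' @param x numeric vector of masked intensities.
#' @return named numeric vector of length 14.
#' @export
histogram_features <- function(x) {
  if (length(x) == 0L) stop("empty intensity vector")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3); m4 <- mean((x - mu)^4)
  rng <- range(x)
  if (diff(rng) > 0) {
    h <- tabulate(pmin(pmax(
      findInterval(x, seq(rng[1], rng[2], length.out = 257),
                   rightmost.closed = TRUE), 1L), 256L), 256L)
    p <- h / length(x)
    p <- p[p > 0]
    ent <- -sum(p * log2(p)); unif <- sum(p^2)
  } else { ent <- 0; unif <- 1 }
  qs <- unname(stats::quantile(x, c(0.1, 0.25, 0.75, 0.9)))
  c(hist_mean = mu,
    hist_variance = m2,
    hist_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    hist_kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    hist_median = stats::median(x),
    hist_min = rng[1], hist_max = rng[2], hist_range = diff(rng),
    hist_p10 = qs[1], hist_p90 = qs[4], hist_iqr = qs[3] - qs[2],
    hist_energy = sum(x^2),
    hist_entropy = ent, hist_uniformity = unif)
}

## ---- matrix families -------------------------------------------------------

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' GLCM features (21, IBSI definitions)
#'
#' @param P normalised symmetric co-occurrence matrix from [build_glcm()].
#' @return named numeric vector of length 21.
#' @export
glcm_features <- function(P) {
  Ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(Ng) * px)
  sig2 <- sum((seq_len(Ng) - mu)^2 * px)
  k_diff <- 0:(Ng - 1)
  p_d <- sapply(k_diff, function(k) sum(P[abs(i - j) == k]))
  mu_d <- sum(k_diff * p_d)
  k_sum <- 2:(2 * Ng)
  p_s <- sapply(k_sum, function(k) sum(P[(i + j) == k]))
  sa <- sum(k_sum * p_s)
  HXY <- -sum(xlog2(P))
  pxpy <- outer(px, px)
  HXY1 <- -sum(ifelse(P > 0 & pxpy > 0, P * log2(pxpy), 0))
  HXY2 <- -sum(xlog2(pxpy))
  HX <- -sum(xlog2(px))
  autoc <- sum(i * j * P)
  c(glcm_autocorrelation = autoc,
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * P),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = if (sig2 > 0) (autoc - mu^2) / sig2 else 1,
    glcm_difference_entropy = -sum(xlog2(p_d)),
    glcm_difference_variance = sum((k_diff - mu_d)^2 * p_d),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_energy = sum(P^2),
    glcm_entropy = HXY,
    glcm_idm = sum(P / (1 + (i - j)^2)),
    glcm_idmn = sum(P / (1 + (i - j)^2 / Ng^2)),
    glcm_id = sum(P / (1 + abs(i - j))),
    glcm_idn = sum(P / (1 + abs(i - j) / Ng)),
    glcm_imc1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    glcm_imc2 = sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)),
    glcm_max_probability = max(P),
    glcm_sum_average = sa,
    glcm_sum_entropy = -sum(xlog2(p_s)),
    glcm_sum_variance = sum((k_sum - sa)^2 * p_s),
    glcm_variance = sig2)
}

# Shared run-length / size-zone feature kernel: M is a level x size count
# matrix and Np the masked voxel count; `prefix` and the 13 suffixes name
# the family.
rl_sz_features <- function(M, Np, prefix, suffixes) {
  Ns <- sum(M)
  i <- row(M); l <- col(M)
  p <- M / Ns
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  vals <- c(
    sum(M / l^2) / Ns,
    sum(M * l^2) / Ns,
    sum(rowSums(M)^2) / Ns,
    sum(colSums(M)^2) / Ns,
    Ns / Np,
    sum(M / i^2) / Ns,
    sum(M * i^2) / Ns,
    sum(M / (i^2 * l^2)) / Ns,
    sum(M * i^2 / l^2) / Ns,
    sum(M * l^2 / i^2) / Ns,
    sum(M * i^2 * l^2) / Ns,
    sum((i - mu_i)^2 * p),
    sum((l - mu_l)^2 * p))
  names(vals) <- paste0(prefix, suffixes)
  vals
}

#' GLRLM features (13, IBSI definitions)
#' @param M run-length count matrix from [build_glrlm()].
#' @param Np masked voxel count (for run percentage).
#' @return named numeric vector of length 13.
#' @export
glrlm_features <- function(M, Np) {
  rl_sz_features(M, Np, "glrlm_",
                 c("sre", "lre", "gln", "rln", "run_percentage", "lgre",
                   "hgre", "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv"))
}

#' GLSZM features (13, IBSI definitions)
#' @param M size-zone count matrix from [build_glszm()].
#' @param Np masked voxel count (for zone percentage).
#' @return named numeric vector of length 13.
#' @export
glszm_features <- function(M, Np) {
  rl_sz_features(M, Np, "glszm_",
                 c("sae", "lae", "gln", "szn", "zone_percentage", "lgze",
                   "hgze", "salge", "sahge", "lalge", "lahge", "glv", "zv"))
}

#' NGTDM features (5, IBSI definitions)
#' @param ngtdm output of [build_ngtdm()].
#' @return named numeric vector of length 5.
#' @export
ngtdm_features <- function(ngtdm) {
  eps <- 1e-12
  p <- ngtdm$p; s <- ngtdm$s; N <- ngtdm$N
  lev <- seq_along(p)
  occ <- which(p > 0)
  Ngp <- length(occ)
  ps <- sum(p * s)
  coarse <- if (ps < eps) 1e6 else min(1 / ps, 1e6)
  if (Ngp > 1) {
    io <- lev[occ]
    pd <- outer(p[occ], p[occ])
    dd <- outer(io, io, `-`)
    contrast <- sum(pd * dd^2) / (Ngp * (Ngp - 1)) * sum(s) / N
    busy_den <- sum(abs(outer(io * p[occ], io * p[occ], `-`)))
    busy <- if (busy_den < eps) 0 else ps / busy_den
    cplx <- sum(abs(dd) * (outer(p[occ] * s[occ], p[occ] * s[occ], `+`)) /
                  (outer(p[occ], p[occ], `+`))) / N
    strg_den <- sum(s)
    strg <- if (strg_den < eps) 0 else sum(outer(p[occ], p[occ], `+`) * dd^2) / strg_den
  } else { contrast <- 0; busy <- 0; cplx <- 0; strg <- 0 }
  c(ngtdm_coarseness = coarse, ngtdm_contrast = contrast,
    ngtdm_busyness = busy, ngtdm_complexity = cplx, ngtdm_strength = strg)
}

## ---- Gabor -----------------------------------------------------------------

# Complex Gabor kernel: carrier of wavelength `lambda` along orientation
# `theta` (radians), Gaussian envelope sigma = 0.56 * lambda, aspect 0.5.
# The real part is made zero-mean so responses ignore the image DC level.
gabor_kernel <- function(lambda, theta) {
  sigma <- 0.56 * lambda
  gamma <- 0.5
  half <- max(2L, ceiling(2.5 * sigma))
  g <- expand.grid(x = -half:half, y = -half:half)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * xr / lambda)
  im <- env * sin(2 * pi * xr / lambda)
  n <- 2L * half + 1L
  re <- re - mean(re)
  list(re = matrix(re, n, n), im = matrix(im, n, n))
}

#' Gabor filter-bank features
#'
#' A 2D bank of 5 scales (wavelengths 3, 3*sqrt(2), 6, 6*sqrt(2), 12 pixels —
#' a half-octave ladder from the minimal wavelength 3) and 6 orientations
#' (k*pi/6). Per filter, the mean magnitude response over masked pixels is
#' pooled over all mask-bearing axial slices; the 12 features are the
#' per-orientation mean and standard deviation of these responses across the
#' 5 scales.
#'
#' @param v a `volume_with_mask` (resampled).
#' @return named numeric vector of length 12.
#' @export
gabor_features <- function(v) {
  stopifnot(inherits(v, "volume_with_mask"))
  zs <- which(apply(v$mask, 3, any))
  if (length(zs) == 0L) stop("empty mask")
  orient <- GABOR_ORIENTATIONS * pi / 180
  waves <- GABOR_WAVELENGTHS
  inplane <- min(apply(which(v$mask, arr.ind = TRUE)[, 1:2, drop = FALSE], 2,
                       function(ix) diff(range(ix)) + 1))
  if (inplane < max(waves))
    warning("lesion thinner in-plane than the largest Gabor wavelength")
  di <- dim(v$intensities)[1]; dj <- dim(v$intensities)[2]
  # per scale: complex kernel (real + i*imag carrier), its padded-FFT per
  # orientation cached for the slice geometry of this volume
  halves <- integer(length(waves)); kf <- vector("list", length(waves))
  npd <- vector("list", length(waves))
  for (si in seq_along(waves)) {
    k0 <- gabor_kernel(waves[si], 0)
    h <- (nrow(k0$re) - 1L) %/% 2L
    halves[si] <- h
    np <- c(stats::nextn(di + 2L * h, c(2, 3, 5)),
            stats::nextn(dj + 2L * h, c(2, 3, 5)))
    npd[[si]] <- np
    kf[[si]] <- lapply(orient, function(th) {
      k <- gabor_kernel(waves[si], th)
      n <- nrow(k$re)
      kc <- matrix(0 + 0i, np[1], np[2])
      kc[seq_len(n), seq_len(n)] <- (k$re + 1i * k$im)[n:1, n:1]
      stats::fft(kc)
    })
  }
  resp_sum <- matrix(0, length(orient), length(waves))
  npix <- 0
  ri <- lapply(halves, function(h) pmin(pmax(seq_len(di + 2L * h) - h, 1L), di))
  rj <- lapply(halves, function(h) pmin(pmax(seq_len(dj + 2L * h) - h, 1L), dj))
  for (z in zs) {
    img <- v$intensities[, , z]
    msk <- v$mask[, , z]
    npix <- npix + sum(msk)
    for (si in seq_along(waves)) {
      h <- halves[si]; np <- npd[[si]]
      emb <- matrix(0, np[1], np[2])
      emb[seq_len(di + 2L * h), seq_len(dj + 2L * h)] <- img[ri[[si]], rj[[si]]]
      P <- stats::fft(emb)
      for (oi in seq_along(orient)) {
        full <- stats::fft(P * kf[[si]][[oi]], inverse = TRUE) / prod(np)
        mag <- Mod(full[(2L * h + 1L):(2L * h + di),
                        (2L * h + 1L):(2L * h + dj), drop = FALSE])
        resp_sum[oi, si] <- resp_sum[oi, si] + sum(mag[msk])
      }
    }
  }
  resp <- resp_sum / npix
  out <- c(rowMeans(resp), apply(resp, 1, stats::sd))
  names(out) <- c(paste0("gabor_mean_", GABOR_ORIENTATIONS),
                  paste0("gabor_sd_", GABOR_ORIENTATIONS))
  out
}

## ---- per-case and cohort extraction ---------------------------------------

#' Default extraction configuration
#'
#' @param target_spacing isotropic resampling spacing in mm.
#' @param ng_levels gray-level counts to quantize at; matrix features are
#'   averaged over these.
#' @param directions in-plane GLCM/GLRLM directions in degrees.
#' @param interp image interpolation for resampling.
#' @return named list.
#' @export
extraction_config <- function(target_spacing = 1,
                              ng_levels = c(8, 16, 24, 32, 40, 48, 64),
                              directions = c(0, 45, 90, 135),
                              interp = "nearest") {
  list(target_spacing = target_spacing, ng_levels = ng_levels,
       directions = directions, interp = interp)
}

#' Extract the 92-feature vector for one case
#'
#' Shape and histogram features come from the raw resampled masked data (no
#' intensity normalisation). Each matrix-family feature is computed at every
#' gray-level count in `config$ng_levels` (GLCM/GLRLM additionally at each
#' direction), then averaged: mean over directions, then mean over levels.
#' Gabor features are computed from the resampled slices. The result follows
#' [feature_catalog()] order exactly.
#'
#' @param v a `volume_with_mask`.
#' @param config list from [extraction_config()].
#' @return named numeric vector of length 92.
#' @export
extract_case <- function(v, config = extraction_config()) {
  res <- tryCatch(
    resample_isotropic(v, config$target_spacing, config$interp),
    error = function(e) stop("case ", v$case_id %||% "?", ": ", conditionMessage(e)))
  # crop to the lesion bounding box (+2 voxels): texture matrices only see
  # masked voxels, and the Gabor responses are pooled over masked pixels only
  bb <- mask_bbox(res$mask)
  d <- dim(res$mask)
  lo <- pmax(bb[, 1] - 2L, 1L); hi <- pmin(bb[, 2] + 2L, d)
  crop <- res
  crop$intensities <- res$intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  crop$mask <- res$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  out_shape <- shape_features(res$mask, res$spacing)
  out_hist <- histogram_features(crop$intensities[crop$mask])
  Np <- sum(crop$mask)

  acc_glcm <- 0; acc_glrlm <- 0; acc_glszm <- 0; acc_ngtdm <- 0
  for (ng in config$ng_levels) {
    q <- equal_probability_quantize(crop, ng)
    gl <- 0; rl <- 0
    for (dir in config$directions) {
      gl <- gl + glcm_features(build_glcm(q, dir))
      rl <- rl + glrlm_features(build_glrlm(q, dir), Np)
    }
    acc_glcm <- acc_glcm + gl / length(config$directions)
    acc_glrlm <- acc_glrlm + rl / length(config$directions)
    acc_glszm <- acc_glszm + glszm_features(build_glszm(q), Np)
    acc_ngtdm <- acc_ngtdm + ngtdm_features(build_ngtdm(q))
  }
  nL <- length(config$ng_levels)
  out <- c(out_shape, out_hist, acc_glcm / nL, acc_glrlm / nL,
           acc_glszm / nL, acc_ngtdm / nL, gabor_features(crop))
  stopifnot(identical(names(out), feature_catalog()$name))
  out
}

#' Extract the feature table for a whole cohort
#'
#' One row per manifest case, columns `case_id`, `batch`, `label`, then the
#' 92 catalog features. Cases are processed in manifest order; output is
#' deterministic for identical input.
#'
#' @param manifest data frame with columns `case_id`, `batch`, `label`,
#'   `image`, `mask` (e.g. from [generate_cohort()] or
#'   [read_cohort_manifest()]).
#' @param config extraction configuration.
#' @param out_csv optional path: write the table as CSV.
#' @param on_error `"stop"` (default) or `"skip"` unreadable/failed cases
#'   (skips are recorded in the `"failed_cases"` attribute).
#' @param verbose log per-case timing via `message()`.
#' @return the feature table data frame.
#' @export
extract_cohort <- function(manifest, config = extraction_config(),
                           out_csv = NULL, on_error = c("stop", "skip"),
                           verbose = FALSE) {
  on_error <- match.arg(on_error)
  rows <- vector("list", nrow(manifest))
  failed <- character(0)
  for (r in seq_len(nrow(manifest))) {
    t0 <- Sys.time()
    feat <- tryCatch({
      v <- read_case(manifest$image[r], manifest$mask[r],
                     case_id = manifest$case_id[r])
      extract_case(v, config)
    }, error = function(e) {
      if (on_error == "stop") stop(e)
      message("skipping ", manifest$case_id[r], ": ", conditionMessage(e))
      NULL
    })
    if (is.null(feat)) { failed <- c(failed, manifest$case_id[r]); next }
    rows[[r]] <- data.frame(case_id = manifest$case_id[r],
                            batch = manifest$batch[r],
                            label = manifest$label[r],
                            as.list(feat), check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("%s: %.2fs", manifest$case_id[r],
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  tab <- do.call(rbind, rows)
  attr(tab, "failed_cases") <- failed
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}
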