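#' Resample a volume and mask to an isotropic grid
#'
#' Both image and mask are resampled by nearest-neighbour interpolation onto a
#' common isotropic grid, preserving physical extent. Nearest-neighbour is the
#' default for the image as well as the mask so that texture analysis consumes
#' unmixed voxel intensities; a linear option is exposed for sensitivity
#' analysis.
#'
#' @param v a `volume_with_mask`.
#' @param target_spacing isotropic output spacing in mm.
#' @param interp `"nearest"` (default) or `"linear"` image interpolation; the
#'   mask is always nearest-neighbour.
#' @return a `volume_with_mask` with equal spacing on all three axes.
#' @export
resample_isotropic <- function(v, target_spacing = 1,
                               interp = c("nearest", "linear")) {
  interp <- match.arg(interp)
  stopifnot(inherits(v, "volume_with_mask"), target_spacing > 0)
  sp <- v$spacing
  if (max(sp) / min(sp) > 20)
    warning("extreme anisotropy (ratio > 20); resampling may be unreliable")
  d <- dim(v$intensities)
  if (all(abs(sp - target_spacing) < 1e-12)) {
    out <- v
    out$spacing <- rep(target_spacing, 3)
    return(out)
  }
  nd <- pmax(1L, as.integer(round(d * sp / target_spacing)))
  # output voxel centres mapped back to input voxel (fractional) coordinates
  coord <- function(k) {
    x <- ((seq_len(nd[k]) - 0.5) * target_spacing) / sp[k] + 0.5
    pmin(pmax(x, 1), d[k])
  }
  cx <- coord(1); cy <- coord(2); cz <- coord(3)
  nx <- pmin(pmax(round(cx), 1L), d[1])
  ny <- pmin(pmax(round(cy), 1L), d[2])
  nz <- pmin(pmax(round(cz), 1L), d[3])
  if (interp == "nearest") {
    img <- v$intensities[nx, ny, nz, drop = FALSE]
  } else {
    img <- trilinear_resample(v$intensities, cx, cy, cz)
  }
  msk <- v$mask[nx, ny, nz, drop = FALSE]
  out <- v
  out$intensities <- img
  out$mask <- msk
  out$spacing <- rep(target_spacing, 3)
  out
}

trilinear_resample <- function(a, cx, cy, cz) {
  d <- dim(a)
  f <- function(c_, dk) {
    lo <- pmin(pmax(floor(c_), 1L), dk - 1L)
    if (dk == 1L) lo <- rep(1L, length(c_))
    list(lo = lo, fr = pmin(pmax(c_ - lo, 0), 1))
  }
  X <- f(cx, d[1]); Y <- f(cy, d[2]); Z <- f(cz, d[3])
  out <- array(0, c(length(cx), length(cy), length(cz)))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- outer(outer(if (dx) X$fr else 1 - X$fr,
                     if (dy) Y$fr else 1 - Y$fr), if (dz) Z$fr else 1 - Z$fr)
    out <- out + w * a[pmin(X$lo + dx, d[1]), pmin(Y$lo + dy, d[2]),
                       pmin(Z$lo + dz, d[3]), drop = FALSE]
  }
  out
}

#' Crop lesion-bearing slices and resize them to a square matrix
#'
#' For every axial slice intersecting the mask, crops the image to that
#' slice's mask bounding box (plus a fractional margin per side) and resizes
#' the crop to `out_size` x `out_size` by bilinear interpolation. Each output
#' slice is tagged with its source case id so downstream cross-validation can
#' keep all slices of a case in the same fold.
#'
#' @param v a `volume_with_mask`.
#' @param out_size output matrix size in pixels (default 224).
#' @param margin fractional bounding-box margin per side (default 0.1).
#' @return list with `slices` (array `out_size x out_size x n_slices`),
#'   `case_id` (per-slice), `slice_index` (source z index).
#' @export
crop_and_resize_slices <- function(v, out_size = 224, margin = 0.1) {
  stopifnot(inherits(v, "volume_with_mask"), out_size >= 8)
  zs <- which(apply(v$mask, 3, any))
  if (length(zs) == 0L) stop("empty mask: no slice intersects the lesion")
  out <- array(0, c(out_size, out_size, length(zs)))
  for (s in seq_along(zs)) {
    z <- zs[s]
    m <- v$mask[, , z]
    idx <- which(m, arr.ind = TRUE)
    r <- range(idx[, 1]); c_ <- range(idx[, 2])
    mr <- ceiling(margin * (diff(r) + 1)); mc <- ceiling(margin * (diff(c_) + 1))
    r <- c(max(1, r[1] - mr), min(nrow(m), r[2] + mr))
    c_ <- c(max(1, c_[1] - mc), min(ncol(m), c_[2] + mc))
    crop <- v$intensities[r[1]:r[2], c_[1]:c_[2], z]
    out[, , s] <- resize_bilinear(crop, out_size, out_size)
  }
  list(slices = out,
       case_id = rep(v$case_id %||% "case", length(zs)),
       slice_index = zs)
}

#' Z-score normalise an image
#'
#' `I_new = (I - mu) / sigma` with the population standard deviation
#' (denominator `n`). Idempotent and invariant to positive affine rescaling of
#' the input.
#'
#' @param image numeric array (any shape).
#' @return array of the same shape with mean 0 and SD 1.
#' @export
zscore_normalize <- function(image) {
  mu <- mean(image)
  sigma <- sqrt(mean((image - mu)^2))
  if (sigma <= 0) stop("constant image: zero standard deviation")
  (image - mu) / sigma
}
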