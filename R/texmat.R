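# Equal-probability quantization and the four texture matrices
# (GLCM, GLRLM, GLSZM, NGTDM).

#' Equal-probability gray-level quantization
#'
#' Discretises masked intensities into `Ng` gray levels using thresholds at
#' the k/Ng empirical quantiles (k = 1..Ng-1, quantile type 1: the smallest
#' observed value whose empirical CDF reaches k/Ng), so that every level holds
#' an (up to ties) equal number of voxels. The mapping depends only on
#' intensity ranks, so it is invariant under any strictly increasing
#' transform of the intensities.
#'
#' @param v a `volume_with_mask` (typically resampled to isotropic voxels).
#' @param Ng number of gray levels (>= 2).
#' @return an object of class `quantized_volume`: list with `levels` (3D
#'   integer array, 0 outside the mask, 1..Ng inside), `Ng`, `thresholds`
#'   (Ng-1 ascending values).
#' @export
equal_probability_quantize <- function(v, Ng) {
  stopifnot(inherits(v, "volume_with_mask"), Ng >= 2)
  x <- v$intensities[v$mask]
  if (length(x) < Ng)
    stop(sprintf("masked voxel count (%d) below Ng (%d)", length(x), Ng))
  ndist <- length(unique(x))
  if (ndist < Ng)
    stop(sprintf("only %d distinct masked intensities for Ng = %d levels",
                 ndist, Ng))
  thr <- unname(stats::quantile(x, probs = seq_len(Ng - 1) / Ng, type = 1))
  # values equal to a threshold map to the lower level
  lev <- as.integer(cut(x, breaks = c(-Inf, thr, Inf), right = TRUE))
  levels <- array(0L, dim(v$intensities))
  levels[v$mask] <- lev
  structure(list(levels = levels, Ng = as.integer(Ng), thresholds = thr),
            class = "quantized_volume")
}

#' @export
print.quantized_volume <- function(x, ...) {
  occ <- tabulate(x$levels[x$levels > 0L], x$Ng)
  cat("Quantized volume: Ng =", x$Ng, "; occupancy", min(occ), "-", max(occ), "\n")
  invisible(x)
}

# In-plane unit offsets for the four classic co-occurrence directions,
# as (row, col) steps within an axial slice.
direction_offset <- function(direction) {
  switch(as.character(direction),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("direction must be one of 0, 45, 90, 135 (degrees)"))
}

# Level pairs (ordered) for an in-plane offset, pooled over all axial slices.
inplane_pairs <- function(L, off) {
  d <- dim(L)
  di <- off[1]; dj <- off[2]
  i1 <- max(1L, 1L - di):min(d[1], d[1] - di)
  j1 <- max(1L, 1L - dj):min(d[2], d[2] - dj)
  if (length(i1) == 0L || length(j1) == 0L)
    return(cbind(integer(0), integer(0)))
  a <- L[i1, j1, , drop = FALSE]
  b <- L[i1 + di, j1 + dj, , drop = FALSE]
  sel <- a > 0L & b > 0L
  cbind(a[sel], b[sel])
}

#' Build a gray-level co-occurrence matrix
#'
#' Co-occurrence counts for the 1-voxel in-plane offset of the given
#' direction, accumulated over every axial slice (both voxels inside the
#' mask; offset partners outside the mask contribute nothing). The matrix is
#' symmetrised (both orderings counted) and normalised to sum 1.
#'
#' @param q a `quantized_volume`.
#' @param direction one of 0, 45, 90, 135 (degrees, in-plane).
#' @return Ng x Ng normalised symmetric matrix.
#' @export
build_glcm <- function(q, direction = 0) {
  stopifnot(inherits(q, "quantized_volume"))
  pr <- inplane_pairs(q$levels, direction_offset(direction))
  if (nrow(pr) == 0L)
    stop("no valid voxel pair for direction ", direction, " (degenerate geometry)")
  Ng <- q$Ng
  cnt <- matrix(tabulate((pr[, 1] - 1L) * Ng + pr[, 2], Ng * Ng), Ng, Ng,
                byrow = TRUE)
  cnt <- cnt + t(cnt)
  cnt / sum(cnt)
}

#' Build a gray-level run length matrix
#'
#' Maximal runs of constant level along the in-plane direction, within the
#' mask, per axial slice. Entry (i, l) counts runs of level i and length l.
#'
#' @inheritParams build_glcm
#' @return Ng x Lmax count matrix.
#' @export
build_glrlm <- function(q, direction = 0) {
  stopifnot(inherits(q, "quantized_volume"))
  L <- q$levels
  d <- dim(L)
  ii <- slice.index(L, 1); jj <- slice.index(L, 2); kk <- slice.index(L, 3)
  lineid <- switch(as.character(direction),
                   "0"   = (kk - 1) * d[1] + ii,            # fixed (i, k), run over j
                   "90"  = (kk - 1) * d[2] + jj,            # fixed (j, k), run over i
                   "45"  = (kk - 1) * (d[1] + d[2]) + (ii + jj),
                   "135" = (kk - 1) * (d[1] + d[2]) + (jj - ii + d[1]),
                   stop("direction must be one of 0, 45, 90, 135 (degrees)"))
  ord <- switch(as.character(direction),
                "0"   = order(lineid, jj),
                "90"  = order(lineid, ii),
                "45"  = order(lineid, jj),
                "135" = order(lineid, jj))
  v <- as.integer(L)[ord]
  ln <- as.integer(lineid)[ord]
  n <- length(v)
  newline <- c(TRUE, ln[-1] != ln[-n])
  start <- newline | v != c(-1L, v[-n])
  starts <- which(start)
  lens <- diff(c(starts, n + 1L))
  levs <- v[starts]
  keep <- levs > 0L
  lens <- lens[keep]; levs <- levs[keep]
  if (length(lens) == 0L) return(matrix(0, q$Ng, 1))
  Lmax <- max(lens)
  matrix(tabulate((levs - 1L) * Lmax + lens, q$Ng * Lmax), q$Ng, Lmax,
         byrow = TRUE)
}

# The 13 positive 26-connectivity offsets (each unordered pair once).
OFFSETS_26_HALF <- local({
  o <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  o <- o[order(o$dk, o$dj, o$di), ]
  o <- as.matrix(o)
  o[(o[, 3] > 0) | (o[, 3] == 0 & o[, 2] > 0) |
      (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0), , drop = FALSE]
})

# Linear-index pairs of 26-adjacent cells for which pred(a, b) holds.
adjacent_pairs_26 <- function(d, pred) {
  arr <- array(seq_len(prod(d)), d)
  out <- vector("list", nrow(OFFSETS_26_HALF))
  for (r in seq_len(nrow(OFFSETS_26_HALF))) {
    off <- OFFSETS_26_HALF[r, ]
    i1 <- max(1L, 1L - off[1]):min(d[1], d[1] - off[1])
    j1 <- max(1L, 1L - off[2]):min(d[2], d[2] - off[2])
    k1 <- max(1L, 1L - off[3]):min(d[3], d[3] - off[3])
    if (!length(i1) || !length(j1) || !length(k1)) next
    a <- arr[i1, j1, k1, drop = FALSE]
    b <- arr[i1 + off[1], j1 + off[2], k1 + off[3], drop = FALSE]
    sel <- pred(a, b)
    out[[r]] <- cbind(a[sel], b[sel])
  }
  do.call(rbind, out)
}

# 26-connected components of constant positive level. Returns a list with
# per-component `level` and `size`, plus the membership labelling array.
label_zones_26 <- function(L) {
  d <- dim(L)
  vox <- which(L > 0L)
  if (length(vox) == 0L) stop("empty mask")
  vid <- array(0L, d); vid[vox] <- seq_along(vox)
  pairs <- adjacent_pairs_26(d, function(a, b) L[a] > 0L & L[a] == L[b])
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(pairs) && nrow(pairs))
    g <- igraph::add_edges(g, rbind(vid[pairs[, 1]], vid[pairs[, 2]]))
  comp <- igraph::components(g)
  lev <- L[vox][match(seq_len(comp$no), comp$membership)]
  list(level = lev, size = comp$csize, membership = comp$membership, vox = vox)
}

# TRUE if the positive cells of `mask` form one 26-connected component.
single_component_26 <- function(mask) {
  z <- label_zones_26(array(as.integer(mask), dim(mask)))
  length(z$size) == 1L
}

#' Build a gray-level size zone matrix
#'
#' Decomposes the mask into 26-connected zones of constant gray level (corner
#' contact counts as connected). Entry (i, z) counts zones of level i and
#' size z voxels.
#'
#' @param q a `quantized_volume`.
#' @return Ng x Zmax count matrix.
#' @export
build_glszm <- function(q) {
  stopifnot(inherits(q, "quantized_volume"))
  zn <- label_zones_26(q$levels)
  Zmax <- max(zn$size)
  matrix(tabulate((zn$level - 1L) * Zmax + zn$size, q$Ng * Zmax), q$Ng, Zmax,
         byrow = TRUE)
}

#' Build a neighbourhood gray tone difference matrix
#'
#' For every masked voxel with at least one masked 26-neighbour, accumulates
#' the absolute difference between its level and the mean level of its masked
#' neighbours into `s` of its level; `p` is the occupancy fraction of each
#' level among those voxels.
#'
#' @param q a `quantized_volume`.
#' @return list with vectors `p` (probabilities, sum 1), `s` (summed absolute
#'   neighbourhood differences), `n` (voxel counts per level), `N` (total).
#' @export
build_ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_volume"))
  L <- q$levels
  d <- dim(L)
  nbr_sum <- array(0, d); nbr_cnt <- array(0L, d)
  arr <- array(seq_len(prod(d)), d)
  for (r in seq_len(nrow(OFFSETS_26_HALF))) {
    off <- OFFSETS_26_HALF[r, ]
    i1 <- max(1L, 1L - off[1]):min(d[1], d[1] - off[1])
    j1 <- max(1L, 1L - off[2]):min(d[2], d[2] - off[2])
    k1 <- max(1L, 1L - off[3]):min(d[3], d[3] - off[3])
    if (!length(i1) || !length(j1) || !length(k1)) next
    a <- as.vector(arr[i1, j1, k1, drop = FALSE])
    b <- as.vector(arr[i1 + off[1], j1 + off[2], k1 + off[3], drop = FALSE])
    la <- L[a]; lb <- L[b]
    sel <- la > 0L & lb > 0L
    a <- a[sel]; b <- b[sel]; la <- la[sel]; lb <- lb[sel]
    nbr_sum[a] <- nbr_sum[a] + lb; nbr_cnt[a] <- nbr_cnt[a] + 1L
    nbr_sum[b] <- nbr_sum[b] + la; nbr_cnt[b] <- nbr_cnt[b] + 1L
  }
  valid <- L > 0L & nbr_cnt > 0L
  if (!any(valid)) stop("no masked voxel has a masked 26-neighbour")
  lev <- L[valid]
  dev <- abs(lev - nbr_sum[valid] / nbr_cnt[valid])
  Ng <- q$Ng
  n_i <- tabulate(lev, Ng)
  s_i <- as.vector(tapply(dev, factor(lev, levels = seq_len(Ng)), sum,
                          default = 0))
  N <- sum(n_i)
  list(p = n_i / N, s = s_i, n = n_i, N = N)
}
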