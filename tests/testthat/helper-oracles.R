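# Independent brute-force oracles for the texture-matrix builders. These are
# deliberately naive (triple loops, recursive flood fill) and share no code
# with the implementation.

qv <- function(lev3d, Ng) {
  structure(list(levels = lev3d, Ng = as.integer(Ng), thresholds = numeric(0)),
            class = "quantized_volume")
}

vol <- function(arr, mask = NULL, spacing = c(1, 1, 1)) {
  if (is.null(mask)) mask <- array(TRUE, dim(arr))
  structure(list(intensities = arr, mask = mask, spacing = spacing,
                 case_id = "oracle"), class = "volume_with_mask")
}

oracle_glcm <- function(L, Ng, off) {
  d <- dim(L)
  cnt <- matrix(0, Ng, Ng)
  for (k in 1:d[3]) for (i in 1:d[1]) for (j in 1:d[2]) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= d[1] && j2 >= 1 && j2 <= d[2] &&
        L[i, j, k] > 0 && L[i2, j2, k] > 0)
      cnt[L[i, j, k], L[i2, j2, k]] <- cnt[L[i, j, k], L[i2, j2, k]] + 1
  }
  cnt <- cnt + t(cnt)
  cnt / sum(cnt)
}

oracle_glrlm <- function(L, Ng, dir) {
  d <- dim(L)
  step <- switch(as.character(dir), "0" = c(0, 1), "90" = c(1, 0),
                 "45" = c(-1, 1), "135" = c(-1, -1))
  res <- matrix(0, Ng, prod(d[1:2]))
  for (k in 1:d[3]) for (i in 1:d[1]) for (j in 1:d[2]) {
    if (L[i, j, k] == 0) next
    pi_ <- i - step[1]; pj <- j - step[2]
    pred_same <- pi_ >= 1 && pi_ <= d[1] && pj >= 1 && pj <= d[2] &&
      L[pi_, pj, k] == L[i, j, k]
    if (pred_same) next
    len <- 0; ci <- i; cj <- j
    while (ci >= 1 && ci <= d[1] && cj >= 1 && cj <= d[2] &&
           L[ci, cj, k] == L[i, j, k]) {
      len <- len + 1; ci <- ci + step[1]; cj <- cj + step[2]
    }
    res[L[i, j, k], len] <- res[L[i, j, k], len] + 1
  }
  keep <- which(colSums(res) > 0)
  if (length(keep) == 0) return(matrix(0, Ng, 1))
  res[, 1:max(keep), drop = FALSE]
}

oracle_zones <- function(L) {
  d <- dim(L)
  lab <- array(0L, d); cur <- 0L; out <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx <- which(L > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1], p[2], p[3]] > 0) next
    cur <- cur + 1L
    stack <- list(p); lab[p[1], p[2], p[3]] <- cur; size <- 0L
    while (length(stack)) {
      q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (o in seq_len(nrow(offs))) {
        np <- q + offs[o, ]
        if (all(np >= 1) && all(np <= d) &&
            L[np[1], np[2], np[3]] == L[q[1], q[2], q[3]] &&
            lab[np[1], np[2], np[3]] == 0L) {
          lab[np[1], np[2], np[3]] <- cur
          stack[[length(stack) + 1L]] <- np
        }
      }
    }
    out[[cur]] <- c(level = L[p[1], p[2], p[3]], size = size)
  }
  do.call(rbind, out)
}

oracle_ngtdm <- function(L, Ng) {
  d <- dim(L)
  s <- numeric(Ng); n <- integer(Ng)
  for (k in 1:d[3]) for (i in 1:d[1]) for (j in 1:d[2]) {
    if (L[i, j, k] == 0) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3] && L[ii, jj, kk] > 0)
        nb <- c(nb, L[ii, jj, kk])
    }
    if (length(nb)) {
      lv <- L[i, j, k]
      s[lv] <- s[lv] + abs(lv - mean(nb))
      n[lv] <- n[lv] + 1L
    }
  }
  list(p = n / sum(n), s = s, n = n, N = sum(n))
}

zone_table <- function(level, size, Ng) {
  Zmax <- max(size)
  matrix(tabulate((level - 1L) * Zmax + size, Ng * Zmax), Ng, Zmax,
         byrow = TRUE)
}

# digital sphere mask of radius r (voxel units)
sphere_mask <- function(r, pad = 4) {
  d <- rep(2 * r + 2 * pad + 1, 3)
  ctr <- rep(r + pad + 1, 3)
  gx <- slice.index(array(0, d), 1) - ctr[1]
  gy <- slice.index(array(0, d), 2) - ctr[2]
  gz <- slice.index(array(0, d), 3) - ctr[3]
  m <- (gx^2 + gy^2 + gz^2) <= r^2
  dim(m) <- d
  m
}
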