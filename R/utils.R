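# Shared internal helpers: seeding, smoothing, morphology.

# Deterministic fan-out of one master seed into per-stage / per-subject seeds
# (Lehmer-style mix, kept below 2^31 so it is a valid R integer seed).
derive_seed <- function(master, k) {
  as.integer(((as.numeric(master) %% 2147483647) * 48271 +
                k * 16807) %% 2147483647)
}

# Separable Gaussian smoothing of a 3-D array; sigma in mm, truncated at 3
# sigma, kernel renormalised (no energy loss at volume edges beyond clipping).
gaussian_smooth3 <- function(arr, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(arr)
  d <- dim(arr)
  for (ax in 1:3) {
    r <- ceiling(3 * sigma_mm / spacing[ax])
    if (r < 1) next
    k <- dnorm(seq(-r, r) * spacing[ax], sd = sigma_mm)
    k <- k / sum(k)
    n <- d[ax]
    # banded convolution matrix with edge renormalisation
    K <- matrix(0, n, n)
    for (j in seq(-r, r)) {
      idx <- seq_len(n)
      tgt <- idx + j
      ok <- tgt >= 1 & tgt <= n
      K[cbind(idx[ok], tgt[ok])] <- k[j + r + 1]
    }
    K <- K / rowSums(K)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- K %*% matrix(a, nrow = da[1])
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

# Binary dilation by `steps` voxels with 26-connectivity (box structuring
# element), as used for lesion-exclusion masks.
dilate_mask3 <- function(mask, steps = 1L) {
  m <- mask != 0
  d <- dim(m)
  for (s in seq_len(steps)) {
    out <- m
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
      out <- out | m[xs, ys, zs]
    }
    m <- out
  }
  m
}

# Distance (mm) from every voxel to a binary mask (0 inside the mask).
mask_distance <- function(mask_vg) {
  d <- cpp_mask_distance(dim(mask_vg$data), mask_vg$spacing,
                         as.logical(mask_vg$data != 0))
  array(d, dim = dim(mask_vg$data))
}

# Cheap content fingerprint for stage logging.
vol_checksum <- function(v) {
  x <- if (inherits(v, "volume_grid")) v$data else v
  sprintf("[n=%d sum=%.6g sd=%.6g]", length(x), sum(x), stats::sd(as.numeric(x)))
}

log_stage <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
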