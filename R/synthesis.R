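#' Nadaraya-Watson kernel regression
#'
#' Direct-summation Gaussian-kernel regression
#' `M(k) = sum_i K((k - t_i)/h) f_i / sum_i K((k - t_i)/h)` with
#' `K(p) = exp(-p^2/2) / sqrt(2*pi)`. Where the denominator underflows, the
#' response of the nearest predictor value is returned (the extrapolation
#' contract that lets single-tissue models predict a constant FLAIR intensity
#' across the whole T1 range).
#'
#' @param t,f numeric vectors of predictor / response intensities (equal
#'   length, at least 1).
#' @param h kernel bandwidth (> 0), in the same units as `t`.
#' @param grid evaluation points.
#' @return numeric vector of predictions, one per grid point.
#' @export
kernel_regress <- function(t, f, h, grid) {
  if (length(t) == 0L || length(t) != length(f))
    stop("t and f must be non-empty vectors of equal length")
  if (!is.finite(h) || h <= 0) stop("bandwidth h must be positive")
  W <- dnorm(outer(grid, t, "-") / h)
  den <- rowSums(W)
  num <- as.numeric(W %*% f)
  out <- ifelse(den > 1e-300, num / den, NA_real_)
  bad <- which(!is.finite(out))
  for (i in bad) out[i] <- f[which.min(abs(t - grid[i]))]
  out
}

#' Fit the per-voxel synthesis model bank
#'
#' For every voxel inside the training brain mask, pools `(t1, flair)`
#' intensity pairs from an `a^3` patch (clipped at volume edges) across all
#' normalised training subjects, with T1 capped at `t_max`, and stores the
#' kernel-regression curve evaluated at the `m`-point grid
#' `k_j = t_max * j / m`. Also fits the median intensity transfer function
#' (see [estimate_transfer()]) and the periventricular cap used to suppress
#' the synthesis of benign bands and caps: WM voxels within `pv_radius_mm` of
#' the ventricles receive a cap equal to the mean training FLAIR intensity of
#' healthy WM in that shell.
#'
#' @param train list of normalised, co-registered [subject_bundle()]s; a
#'   single subject is accepted with a warning (the transfer-function median
#'   degenerates to that subject's map).
#' @param m curve evaluation count (default 100).
#' @param t_max T1 intensity cap in normalised units (default 1500).
#' @param h kernel bandwidth in normalised units (default 50).
#' @param a training patch edge in voxels (default 5).
#' @param pv_radius_mm radius of the periventricular shell (default 15).
#' @param verbose log stage progress.
#' @return an object of class `"synthesis_bank"`.
#' @export
fit_model_bank <- function(train, m = 100L, t_max = 1500, h = 50, a = 5L,
                           pv_radius_mm = 15, verbose = FALSE) {
  if (length(train) < 1L) stop("empty training cohort")
  if (length(train) < 2L)
    warning("single training subject: per-voxel models and the transfer ",
            "median are fitted from one image pair")
  ref <- train[[1L]]
  for (s in train) stopifnot_lattice(ref$t1, s$t1, what = "training subjects")
  shp <- dim(ref$t1$data)

  t_list <- lapply(train, function(s) pmin(s$t1$data, t_max))
  f_list <- lapply(train, function(s) s$flair$data)

  brain <- Reduce(`|`, lapply(train, function(s) s$t1$data > 0 | s$flair$data > 0))
  fit_idx <- which(brain)
  log_stage(verbose, "synthesis bank: fitting %d voxels (m=%d, h=%g, a=%d) %s",
            length(fit_idx), m, h, a, vol_checksum(t_list[[1L]]))
  fit <- cpp_fit_nw_bank(shp, fit_idx, t_list, f_list,
                         as.integer(a), as.integer(m), t_max, h)
  index_map <- array(0L, shp)
  index_map[fit_idx] <- seq_along(fit_idx)

  bank <- structure(list(
    curves = fit$curves, index_map = index_map, flagged = fit$flagged,
    m = as.integer(m), t_max = t_max, h = h, a = as.integer(a),
    spacing = ref$t1$spacing, shape = shp,
    transfer = NULL, pv_cap = NULL, pv_shell = NULL,
    n_train = length(train)), class = "synthesis_bank")

  # transfer function from the training subjects' own (uncorrected) syntheses
  synth0 <- lapply(train, function(s)
    synthesise(s$t1, bank, apply_transfer = FALSE, apply_cap = FALSE))
  bank$transfer <- estimate_transfer(synth0, lapply(train, `[[`, "flair"))

  # periventricular cap: majority ventricle mask and WM mask over training
  vent_freq <- Reduce(`+`, lapply(train, function(s) s$ventricle_mask$data)) /
    length(train)
  vent <- volume_grid((vent_freq >= 0.5) * 1, ref$t1$spacing)
  wm_freq <- Reduce(`+`, lapply(train, function(s) s$wm_prob$data)) / length(train)
  dvent <- mask_distance(vent)
  shell <- wm_freq > 0.5 & dvent <= pv_radius_mm & dvent > 0
  cap <- array(Inf, shp)
  if (any(shell)) {
    cap_value <- mean(vapply(f_list, function(f) mean(f[shell]), 0))
    cap[shell] <- cap_value
  }
  bank$pv_cap <- volume_grid(ifelse(is.finite(cap), cap, 0), ref$t1$spacing)
  bank$pv_shell <- volume_grid(shell * 1, ref$t1$spacing)
  attr(bank$pv_cap, "cap_is_infinite_off_shell") <- TRUE
  bank
}

#' @export
print.synthesis_bank <- function(x, ...) {
  cat(sprintf(paste0("<synthesis_bank> %d voxel curves (m=%d, t_max=%g, h=%g, ",
                     "a=%d), %d training subjects, %d flagged\n"),
              ncol(x$curves), x$m, x$t_max, x$h, x$a, x$n_train,
              sum(x$flagged)))
  invisible(x)
}

#' Estimate the synthetic-to-FLAIR intensity transfer function
#'
#' Kernel regression smooths the synthetic image towards the mean, compressing
#' the WM/GM contrast. Per training subject, the monotone quantile map sending
#' the intensity distribution of the synthetic image onto that of its true
#' FLAIR is computed over brain (nonzero) voxels and sampled at fixed knots;
#' the stored correction is the pointwise median across subjects.
#'
#' @param synthetic_train,flair_train paired lists of [volume_grid()]s.
#' @param knots sampling knots in normalised units (default 256 points over
#'   `[0, 2000]`).
#' @return an object of class `"transfer_function"`.
#' @export
estimate_transfer <- function(synthetic_train, flair_train,
                              knots = seq(0, 2000, length.out = 256L)) {
  n <- length(synthetic_train)
  stopifnot(n == length(flair_train), n >= 1L)
  if (n < 2L)
    warning("fewer than 2 subjects: transfer median is a single function")
  p <- seq(0, 1, length.out = 1001L)
  per_subject <- vapply(seq_len(n), function(i) {
    s <- synthetic_train[[i]]$data
    f <- flair_train[[i]]$data
    mask <- s > 0 | f > 0
    qs <- quantile(s[mask], p, names = FALSE)
    qf <- quantile(f[mask], p, names = FALSE)
    # collapse flat quantile stretches so the map is a function
    keep <- !duplicated(qs)
    qs_u <- qs[keep]
    qf_u <- vapply(split(qf, cumsum(keep)), mean, 0)
    approx(qs_u, qf_u, xout = knots, rule = 2)$y
  }, numeric(length(knots)))
  med <- apply(per_subject, 1L, median)
  structure(list(knots = knots, per_subject = per_subject, median = med),
            class = "transfer_function")
}

#' Apply a transfer function to intensities
#'
#' Linear interpolation of the median curve between knots; constant
#' extrapolation beyond the knot range.
#'
#' @param x numeric vector/array of intensities.
#' @param tf a `"transfer_function"`.
#' @return corrected intensities, same shape as `x`.
#' @export
apply_transfer <- function(x, tf) {
  out <- approx(tf$knots, tf$median, xout = as.numeric(x), rule = 2)$y
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Synthesise a pseudo-healthy FLAIR volume
#'
#' Per voxel, the (capped) normalised T1 intensity is turned into the curve
#' index `i = ceiling(m * t / t_max)` clamped to `[1, m]` and the stored
#' curve value is read out; the transfer correction is applied; finally WM
#' voxels in the periventricular shell are capped at the expected healthy WM
#' intensity (`min(S, cap)`), so benign training bands and caps are never
#' synthesised as lesion-like hyperintensity.
#'
#' @param t1 normalised T1 [volume_grid()] on the bank lattice.
#' @param bank a `"synthesis_bank"`.
#' @param apply_transfer,apply_cap stage switches (both `TRUE` in the
#'   pipeline; disabled internally while estimating the transfer function).
#' @return the synthetic FLAIR [volume_grid()]; background and flagged
#'   sentinel voxels are 0.
#' @export
synthesise <- function(t1, bank, apply_transfer = TRUE, apply_cap = TRUE) {
  stopifnot(inherits(bank, "synthesis_bank"))
  if (!identical(dim(t1$data), bank$shape))
    stop("t1 volume does not match the bank lattice")
  out <- array(0, bank$shape)
  sel <- which(bank$index_map > 0L)
  if (length(sel)) {
    tcap <- pmin(pmax(t1$data[sel], 0), bank$t_max)
    i <- pmin(pmax(ceiling(bank$m * tcap / bank$t_max), 1L), bank$m)
    out[sel] <- bank$curves[cbind(i, bank$index_map[sel])]
  }
  if (apply_transfer && !is.null(bank$transfer))
    out[sel] <- approx(bank$transfer$knots, bank$transfer$median,
                       xout = out[sel], rule = 2)$y
  if (apply_cap && !is.null(bank$pv_shell)) {
    shell <- bank$pv_shell$data > 0
    out[shell] <- pmin(out[shell], bank$pv_cap$data[shell])
  }
  flag_idx <- which(bank$index_map > 0L)[bank$flagged[bank$index_map[bank$index_map > 0L]]]
  if (length(flag_idx)) out[flag_idx] <- 0
  volume_grid(out, t1$spacing)
}

#' Synthesis-residual abnormality map
#'
#' `L^SYN = F - S`: the voxel-wise signed difference between the subject's
#' true FLAIR and its (transfer-corrected, capped) pseudo-healthy synthetic
#' FLAIR. Near zero in healthy tissue, large and positive inside
#' hyperintense pathology. Any residual registration between `S` and `F` is
#' an upstream concern; volumes must already share the lattice.
#'
#' @param flair,synthetic [volume_grid()]s on one lattice.
#' @return the signed difference [volume_grid()].
#' @export
compute_lsyn <- function(flair, synthetic) {
  stopifnot_lattice(flair, synthetic)
  vg_like(flair, flair$data - synthetic$data)
}
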