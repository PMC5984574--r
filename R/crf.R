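#' Dense-CRF parameters
#'
#' The refinement stage minimises (approximately, by mean field) the energy
#' of a fully connected two-label Potts model over the FLAIR volume with two
#' Gaussian pairwise kernels: a smoothness kernel
#' `w1 * exp(-|p_i - p_j|^2 / 2 sigma_alpha^2)` and an appearance kernel
#' `w2 * exp(-|p_i - p_j|^2 / 2 sigma_beta^2 - (I_i - I_j)^2 / 2 sigma_gamma^2)`.
#' `w2` and `sigma_gamma` are the two tuned values (defaults 8 and 2.5); the
#' remaining defaults are declared package choices. `sigma_gamma` is
#' expressed on a 0-255 intensity scale; [meanfield_crf()] rescales the
#' intensity volume accordingly.
#'
#' @param w1 smoothness kernel weight.
#' @param w2 appearance kernel weight (default 8).
#' @param sigma_alpha,sigma_beta spatial kernel SDs in mm (default 3).
#' @param sigma_gamma appearance intensity SD on the 0-255 scale (default 2.5).
#' @param n_iters mean-field iterations (default 5).
#' @param tau unary temperature: score at which the lesion probability
#'   reaches `1 - exp(-1)`. `NULL` means "set from the training cohort"
#'   (90th percentile of positive scores).
#' @param eps probability clip for the unary bridge.
#' @return an object of class `"crf_params"`.
#' @export
crf_params <- function(w1 = 1, w2 = 8, sigma_alpha = 3, sigma_beta = 3,
                       sigma_gamma = 2.5, n_iters = 5L, tau = NULL,
                       eps = 1e-6) {
  stopifnot(w1 >= 0, w2 >= 0, sigma_alpha > 0, sigma_beta > 0,
            sigma_gamma > 0, n_iters >= 1, eps > 0, eps < 0.5,
            is.null(tau) || tau > 0)
  structure(list(w1 = w1, w2 = w2, sigma_alpha = sigma_alpha,
                 sigma_beta = sigma_beta, sigma_gamma = sigma_gamma,
                 n_iters = as.integer(n_iters), tau = tau, eps = eps),
            class = "crf_params")
}

#' Unary potentials from the one-class score map
#'
#' Bridges `L^SVM` to the CRF: `p_lesion = 1 - exp(-s / tau)` clipped to
#' `[eps, 1 - eps]`, and the two-label negative-log unaries
#' `(-log(1 - p), -log p)`. A zero score therefore strongly favours
#' background; `s = tau` gives `p = 1 - exp(-1)`.
#'
#' @param lsvm nonnegative score [volume_grid()].
#' @param tau unary temperature (> 0).
#' @param eps probability clip.
#' @return list with [volume_grid()]s `u0` (background) and `u1` (lesion).
#' @export
build_unary <- function(lsvm, tau, eps = 1e-6) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (min(lsvm$data) < 0) stop("lsvm scores must be nonnegative")
  p <- 1 - exp(-lsvm$data / tau)
  p <- pmin(pmax(p, eps), 1 - eps)
  list(u0 = vg_like(lsvm, -log(1 - p)), u1 = vg_like(lsvm, -log(p)))
}

#' Mean-field inference on the dense CRF
#'
#' Parallel mean-field updates for `n_iters` iterations on the model of
#' [crf_params()], with both pairwise kernels spatially truncated at 3 sigma.
#' The intensity volume is linearly mapped to `[0, 255]` before the
#' appearance term, matching the scale on which `sigma_gamma` is expressed.
#' For tractability, updates run on the set of voxels whose initial lesion
#' belief exceeds 1e-3, dilated by the kernel window (messages are still
#' accumulated over every voxel in the window); all other voxels keep their
#' unary marginal, which the pairwise terms could not move.
#'
#' @param unary list of `u0`/`u1` [volume_grid()]s from [build_unary()].
#' @param intensity the (normalised) FLAIR [volume_grid()].
#' @param params a [crf_params()].
#' @param active_eps initial-belief threshold for the active set; set to 0 to
#'   update every voxel (used against the exact oracle on tiny grids).
#' @return binary [volume_grid()] of labels; the final lesion marginals are
#'   attached as attribute `"q1"`.
#' @export
meanfield_crf <- function(unary, intensity, params = crf_params(),
                          active_eps = 1e-3) {
  stopifnot(inherits(params, "crf_params"))
  stopifnot_lattice(unary$u0, unary$u1, intensity)
  I <- crf_intensity_scale(intensity$data)
  res <- cpp_meanfield(dim(I), intensity$spacing,
                       as.numeric(unary$u0$data), as.numeric(unary$u1$data),
                       as.numeric(I),
                       params$w1, params$w2, params$sigma_alpha,
                       params$sigma_beta, params$sigma_gamma,
                       params$n_iters, active_eps)
  out <- vg_like(intensity, array(as.numeric(res$labels), dim(I)))
  attr(out, "q1") <- array(res$q1, dim(I))
  out
}

crf_intensity_scale <- function(I) {
  mx <- max(I)
  if (mx > 0) I * (255 / mx) else I
}

#' Exact MAP labelling of the dense CRF on tiny volumes
#'
#' Exhaustive minimum-energy labelling of the same dense model, used as the
#' ground-truth oracle for the mean-field approximation. Enforces at most
#' 4096 labellings (12 voxels).
#'
#' @inheritParams meanfield_crf
#' @return binary [volume_grid()]; the minimum energy is attached as
#'   attribute `"energy"`.
#' @export
exact_map_small <- function(unary, intensity, params = crf_params()) {
  stopifnot(inherits(params, "crf_params"))
  stopifnot_lattice(unary$u0, unary$u1, intensity)
  n <- prod(dim(intensity$data))
  if (2^n > 4096) stop("volume too large for exhaustive enumeration (> 12 voxels)")
  I <- crf_intensity_scale(intensity$data)
  res <- cpp_crf_enum(dim(I), intensity$spacing,
                      as.numeric(unary$u0$data), as.numeric(unary$u1$data),
                      as.numeric(I),
                      params$w1, params$w2, params$sigma_alpha,
                      params$sigma_beta, params$sigma_gamma)
  out <- vg_like(intensity, array(as.numeric(res$labels), dim(I)))
  attr(out, "energy") <- res$energy
  out
}

# unbounded (<= 27 voxel) enumeration, for validating mean field in tests
crf_enum_map <- function(unary, intensity, params) {
  I <- crf_intensity_scale(intensity$data)
  res <- cpp_crf_enum(dim(I), intensity$spacing,
                      as.numeric(unary$u0$data), as.numeric(unary$u1$data),
                      as.numeric(I),
                      params$w1, params$w2, params$sigma_alpha,
                      params$sigma_beta, params$sigma_gamma)
  out <- vg_like(intensity, array(as.numeric(res$labels), dim(I)))
  attr(out, "energy") <- res$energy
  out
}

# energy of an arbitrary labelling under the same model (test helper)
crf_energy <- function(unary, intensity, labels, params) {
  I <- crf_intensity_scale(intensity$data)
  cpp_crf_energy(dim(I), intensity$spacing,
                 as.numeric(unary$u0$data), as.numeric(unary$u1$data),
                 as.numeric(I), as.integer(labels),
                 params$w1, params$w2, params$sigma_alpha,
                 params$sigma_beta, params$sigma_gamma)
}
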