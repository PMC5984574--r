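#' Fit a two-component Gaussian mixture by EM
#'
#' Expectation-maximisation for a 1-D two-component Gaussian mixture, the
#' per-voxel model of healthy FLAIR intensity (one component when the voxel
#' sits inside a tissue class, two when it straddles a boundary). Zero
#' intensities (background padding) are discarded first. Initialisation is a
#' deterministic split at the sample median with equal weights, so fits are
#' reproducible without randomness; `seed` is accepted for interface
#' stability and unused. Component SDs are floored at `sigma_floor` to
#' prevent collapse.
#'
#' @param samples numeric intensity sample (>= 8 nonzero values for a true
#'   mixture fit; fewer fall back to a single Gaussian duplicated into both
#'   components).
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @param sigma_floor minimum component SD (normalised units).
#' @param seed unused (deterministic initialisation).
#' @return an object of class `"voxel_gmm"`: `w`, `mu`, `sigma`, the
#'   per-iteration observed-data `loglik` trace, `iterations`, `converged`.
#' @export
em_fit_two_component <- function(samples, tol = 1e-6, max_iter = 200L,
                                 sigma_floor = 1, seed = NULL) {
  x <- samples[samples != 0]
  if (length(x) == 0L) stop("no nonzero samples to fit")
  if (length(x) < 8L) {
    s <- max(sigma_floor, sd(x))
    if (!is.finite(s)) s <- sigma_floor
    return(structure(list(w = c(0.5, 0.5), mu = rep(mean(x), 2L),
                          sigma = rep(s, 2L), loglik = numeric(0),
                          iterations = 0L, converged = TRUE,
                          fallback = TRUE), class = "voxel_gmm"))
  }
  fit <- cpp_em_fit(x, rep(1, length(x)), tol, as.integer(max_iter),
                    sigma_floor)
  structure(list(w = fit$w, mu = fit$mu, sigma = fit$sigma,
                 loglik = fit$loglik, iterations = fit$iterations,
                 converged = fit$converged, fallback = FALSE),
            class = "voxel_gmm")
}

#' @export
print.voxel_gmm <- function(x, ...) {
  cat(sprintf("<voxel_gmm> w = (%.3f, %.3f), mu = (%.4g, %.4g), sigma = (%.4g, %.4g)%s\n",
              x$w[1], x$w[2], x$mu[1], x$mu[2], x$sigma[1], x$sigma[2],
              if (isTRUE(x$fallback)) " [single-Gaussian fallback]" else ""))
  invisible(x)
}

#' Fit the per-voxel GMM bank
#'
#' For every voxel inside the training brain mask, pools nonzero FLAIR
#' intensities from a `b^3` patch (clipped at edges) across all normalised
#' training subjects and fits the two-component mixture; voxels with fewer
#' than 8 pooled samples get the single-Gaussian fallback. Pooled samples
#' are histogrammed at 1-normalised-unit resolution before the (weighted) EM.
#'
#' @param flair_train list of normalised FLAIR [volume_grid()]s (a single
#'   volume is accepted with a warning).
#' @param b patch edge in voxels (default 5).
#' @inheritParams em_fit_two_component
#' @param verbose log stage progress.
#' @return an object of class `"gmm_bank"`.
#' @export
fit_gmm_bank <- function(flair_train, b = 5L, tol = 1e-6, max_iter = 200L,
                         sigma_floor = 1, seed = NULL, verbose = FALSE) {
  if (length(flair_train) < 1L) stop("empty training set")
  if (length(flair_train) < 2L)
    warning("single training volume: voxel mixtures are fitted from one image")
  ref <- flair_train[[1L]]
  for (v in flair_train) stopifnot_lattice(ref, v, what = "training volumes")
  shp <- dim(ref$data)
  f_list <- lapply(flair_train, `[[`, "data")
  brain <- Reduce(`|`, lapply(f_list, function(f) f > 0))
  fit_idx <- which(brain)
  max_int <- max(vapply(f_list, max, 0), 100)
  log_stage(verbose, "GMM bank: fitting %d voxels (b=%d) %s",
            length(fit_idx), b, vol_checksum(f_list[[1L]]))
  fit <- cpp_fit_gmm_bank(shp, fit_idx, f_list, as.integer(b), tol,
                          as.integer(max_iter), sigma_floor, 1.0,
                          max_int * 1.05)
  index_map <- array(0L, shp)
  index_map[fit_idx] <- seq_along(fit_idx)
  structure(list(params = fit$params, index_map = index_map,
                 iterations = fit$iterations, converged = fit$converged,
                 b = as.integer(b), tol = tol, sigma_floor = sigma_floor,
                 spacing = ref$spacing, shape = shp,
                 n_train = length(flair_train)), class = "gmm_bank")
}

#' @export
print.gmm_bank <- function(x, ...) {
  cat(sprintf("<gmm_bank> %d voxel mixtures (b=%d), %d training volumes, %.1f%% converged\n",
              ncol(x$params), x$b, x$n_train, 100 * mean(x$converged)))
  invisible(x)
}

# mixture density at f for parameter columns p = (w1 w2 mu1 mu2 s1 s2)
gmm_density <- function(f, p) {
  p[1L, ] * dnorm(f, p[3L, ], p[5L, ]) + p[2L, ] * dnorm(f, p[4L, ], p[6L, ])
}

#' GMM abnormality map
#'
#' For voxels whose FLAIR intensity is at least 1000 (the normalised WM/GM
#' midpoint), computes the shifted negative log-density of the fitted healthy
#' mixture: `-log(d + eps)` anchored by subtracting its minimum over the
#' brain and floored at 0, so healthy tissue sits near 0 and hyperintense
#' outliers score high on a scale comparable across subjects. Voxels below
#' 1000 are exactly 0, restricting detection to hyperintensities. The
#' `"density"` variant returns the raw mixture density instead (zeroed below
#' 1000), matching the printed form of the likelihood.
#'
#' @param flair normalised FLAIR [volume_grid()] on the bank lattice.
#' @param bank a `"gmm_bank"`.
#' @param variant `"neglog"` (default) or `"density"`.
#' @param threshold hyperintensity gate (1000 normalised units).
#' @param eps log guard.
#' @return abnormality [volume_grid()], nonnegative for the default variant.
#' @export
compute_lflair <- function(flair, bank, variant = c("neglog", "density"),
                           threshold = 1000, eps = 1e-300) {
  variant <- match.arg(variant)
  stopifnot(inherits(bank, "gmm_bank"))
  if (!identical(dim(flair$data), bank$shape))
    stop("flair volume does not match the bank lattice")
  out <- array(0, bank$shape)
  sel <- which(bank$index_map > 0L)
  if (length(sel)) {
    f <- flair$data[sel]
    p <- bank$params[, bank$index_map[sel], drop = FALSE]
    d <- gmm_density(f, p)
    if (variant == "density") {
      out[sel] <- ifelse(f >= threshold, d, 0)
    } else {
      neglog <- -log(d + eps)
      neglog <- neglog - min(neglog)        # anchor healthy tissue near 0
      out[sel] <- pmax(neglog, 0)
      out[sel][f < threshold] <- 0          # hard zero below the midpoint
    }
  }
  vg_like(flair, out)
}
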