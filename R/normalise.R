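#' Refine a tissue intensity sample for normalisation
#'
#' Keeps only voxels whose tissue probability exceeds `prob_threshold`
#' (default 0.95), then keeps the intensities inside the central 95% interval
#' of that sample, removing outliers. The surviving sample is highly likely
#' to be healthy tissue of the requested class, which is what makes the
#' derived fixed point invariant to lesion load: hyperintense lesion voxels
#' either lose tissue probability in real segmentations or fall outside the
#' central interval.
#'
#' @param volume intensity [volume_grid()].
#' @param tissue_prob probability map in `[0, 1]` on the same lattice.
#' @param prob_threshold probability cut (strict `>`).
#' @param interval `"percentile"` (central 2.5-97.5 empirical percentiles,
#'   the default) or `"sd"` (mean +/- 1.96 SD).
#' @param min_n minimum surviving sample size.
#' @return numeric vector of surviving intensities.
#' @export
refine_tissue_sample <- function(volume, tissue_prob, prob_threshold = 0.95,
                                 interval = c("percentile", "sd"),
                                 min_n = 50L) {
  interval <- match.arg(interval)
  stopifnot_lattice(volume, tissue_prob)
  if (min(tissue_prob$data) < 0 || max(tissue_prob$data) > 1)
    stop("tissue probabilities must lie in [0, 1]")
  x <- volume$data[tissue_prob$data > prob_threshold]
  if (length(x) == 0L)
    stop(sprintf("no voxel exceeds tissue probability %g; ", prob_threshold),
         "use a coarser phantom or a lower threshold")
  bounds <- if (interval == "percentile") {
    quantile(x, c(0.025, 0.975), names = FALSE)
  } else {
    mean(x) + c(-1.96, 1.96) * sd(x)
  }
  x <- x[x >= bounds[1] & x <= bounds[2]]
  if (length(x) < min_n)
    stop(sprintf("only %d voxels survive tissue refinement (minimum %d); ",
                 length(x), min_n),
         "use a coarser phantom or a lower threshold")
  x
}

#' Compute the WM/GM intensity fixed point
#'
#' The means of the refined WM and GM samples are averaged into a single
#' fixed point; the linear scale factor maps it to the arbitrary value 1000.
#'
#' @inheritParams refine_tissue_sample
#' @param wm_prob,gm_prob tissue probability maps.
#' @param target the normalised value of the fixed point (1000).
#' @return an object of class `"fixed_point_result"` with `wm_mean`,
#'   `gm_mean`, `fixed_point` and `scale`.
#' @export
compute_fixed_point <- function(volume, wm_prob, gm_prob,
                                prob_threshold = 0.95,
                                interval = c("percentile", "sd"),
                                min_n = 50L, target = 1000) {
  interval <- match.arg(interval)
  wm <- refine_tissue_sample(volume, wm_prob, prob_threshold, interval, min_n)
  gm <- refine_tissue_sample(volume, gm_prob, prob_threshold, interval, min_n)
  wm_mean <- mean(wm)
  gm_mean <- mean(gm)
  fixed_point <- (wm_mean + gm_mean) / 2
  if (!is.finite(fixed_point) || fixed_point <= 0)
    stop("fixed point is not strictly positive")
  structure(list(wm_mean = wm_mean, gm_mean = gm_mean,
                 fixed_point = fixed_point, scale = target / fixed_point),
            class = "fixed_point_result")
}

#' @export
print.fixed_point_result <- function(x, ...) {
  cat(sprintf("<fixed_point_result> WM %.4g, GM %.4g, fixed point %.4g, scale %.6g\n",
              x$wm_mean, x$gm_mean, x$fixed_point, x$scale))
  invisible(x)
}

#' Linearly rescale a volume so its fixed point sits at 1000
#'
#' @param volume intensity [volume_grid()].
#' @param fp a `"fixed_point_result"` from [compute_fixed_point()].
#' @return the rescaled [volume_grid()].
#' @export
normalise_volume <- function(volume, fp) {
  stopifnot(inherits(fp, "fixed_point_result"),
            is.finite(fp$scale), fp$scale > 0)
  vg_like(volume, volume$data * fp$scale)
}

#' Normalise the T1 and FLAIR volumes of a subject bundle
#'
#' T1 and FLAIR are normalised independently, each with its own fixed point
#' derived from the bundle's probability maps.
#'
#' @param bundle a [subject_bundle()].
#' @param ... passed to [compute_fixed_point()].
#' @return the bundle with normalised `t1` and `flair`; the two
#'   `"fixed_point_result"`s are attached as attribute `"fixed_points"`.
#' @export
normalise_bundle <- function(bundle, ...) {
  fp_t1 <- compute_fixed_point(bundle$t1, bundle$wm_prob, bundle$gm_prob, ...)
  fp_fl <- compute_fixed_point(bundle$flair, bundle$wm_prob, bundle$gm_prob, ...)
  bundle$t1 <- normalise_volume(bundle$t1, fp_t1)
  bundle$flair <- normalise_volume(bundle$flair, fp_fl)
  attr(bundle, "fixed_points") <- list(t1 = fp_t1, flair = fp_fl)
  bundle
}
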