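#' Parameters for the synthetic phantom generator
#'
#' The generator emulates the statistical structure the segmentation method
#' assumes: co-registered T1/FLAIR pairs in a common space with WM/GM/CSF
#' intensity classes (T1: bright WM, darker GM, dark CSF; FLAIR: suppressed
#' CSF, bright GM, intermediate WM), spherical hyperintense lesions in the
#' WM that are hypointense on T1, periventricular "bands and caps" FLAIR
#' brightening in healthy subjects, partial-volume smoothing and additive
#' noise. Geometry is concentric shells (CSF "ventricle" core, WM shell, GM
#' rim) — the method is voxel-wise in a common space, so any reproducible
#' layout containing the three tissues exercises every stage.
#'
#' Intensities are generated in arbitrary raw units; the pipeline's
#' normalisation maps the WM/GM midpoint to 1000. Per-class standard
#' deviations model tissue texture; `noise_sd` is additive scanner noise.
#'
#' @param shape voxel dimensions (default 48^3).
#' @param spacing voxel size in mm (scalar or length 3).
#' @param t1_means,t1_sds,flair_means,flair_sds named per-class (`wm`, `gm`,
#'   `csf`) intensity means / SDs in raw units.
#' @param n_lesions number of spherical lesions for pathological subjects.
#' @param lesion_radius_range min/max lesion radius in mm.
#' @param lesion_flair_contrast additive FLAIR offset inside lesions (raw
#'   units, positive: hyperintense).
#' @param lesion_t1_contrast additive T1 offset inside lesions (negative:
#'   hypointense).
#' @param band_cap_intensity additive FLAIR offset in the 2-voxel
#'   periventricular WM rim of healthy subjects (benign "bands and caps").
#' @param noise_sd additive Gaussian noise SD (raw units), head voxels only.
#' @param pv_smoothing_sigma partial-volume smoothing of the noise-free tissue
#'   image, in mm (0 disables).
#' @param seed integer; identical params + seed give bit-identical subjects.
#' @return an object of class `"phantom_params"`.
#' @export
phantom_params <- function(shape = c(48L, 48L, 48L),
                           spacing = c(1, 1, 1),
                           t1_means = c(wm = 0.80, gm = 0.60, csf = 0.25),
                           t1_sds = c(wm = 0.05, gm = 0.04, csf = 0.03),
                           flair_means = c(wm = 0.65, gm = 0.80, csf = 0.20),
                           flair_sds = c(wm = 0.04, gm = 0.04, csf = 0.03),
                           n_lesions = 3L,
                           lesion_radius_range = c(2, 4),
                           lesion_flair_contrast = 0.25,
                           lesion_t1_contrast = -0.15,
                           band_cap_intensity = 0.12,
                           noise_sd = 0.02,
                           pv_smoothing_sigma = 0.5,
                           seed = 1L) {
  shape <- as.integer(rep(shape, length.out = 3L))
  spacing <- as.numeric(rep(spacing, length.out = 3L))
  stopifnot(all(shape >= 8L), all(spacing > 0),
            lesion_radius_range[1] >= min(spacing),
            all(is.finite(c(lesion_flair_contrast, lesion_t1_contrast))),
            noise_sd >= 0, n_lesions >= 0)
  structure(list(
    shape = shape, spacing = spacing,
    t1_means = t1_means, t1_sds = t1_sds,
    flair_means = flair_means, flair_sds = flair_sds,
    n_lesions = as.integer(n_lesions),
    lesion_radius_range = as.numeric(lesion_radius_range),
    lesion_flair_contrast = lesion_flair_contrast,
    lesion_t1_contrast = lesion_t1_contrast,
    band_cap_intensity = band_cap_intensity,
    noise_sd = noise_sd,
    pv_smoothing_sigma = pv_smoothing_sigma,
    seed = as.integer(seed)), class = "phantom_params")
}

# Concentric-shell radii (mm) derived from the volume size.
phantom_radii <- function(params) {
  ext <- min(params$shape * params$spacing)
  c(ventricle = ext / 8, wm = ext / 3, gm = ext * 5 / 12)
}

#' Generate one synthetic subject
#'
#' Builds the concentric-shell phantom: CSF core ("ventricles"), WM shell, GM
#' rim, optional spherical WM lesions (hyperintense on FLAIR, hypointense on
#' T1), partial-volume smoothing of the tissue image, then per-class texture
#' and additive noise. Lesion voxels keep a reduced WM probability (0.6) in
#' the generated probability maps, mirroring the imperfect tissue
#' segmentations real anatomical pipelines produce inside lesions. The atlas
#' member is the analytic periventricular prior `exp(-d / 5 mm)` of ventricle
#' distance `d` (zero inside the ventricles and outside the head).
#'
#' @param params a [phantom_params()].
#' @param healthy logical; if `TRUE`, no lesions are placed and the benign
#'   periventricular band/cap brightening is added to FLAIR instead.
#' @return a [subject_bundle()] whose `lesion_truth` is always present
#'   (all-zero for healthy subjects).
#' @export
generate_subject <- function(params, healthy = FALSE) {
  stopifnot(inherits(params, "phantom_params"))
  set.seed(params$seed)
  shp <- params$shape
  sp <- params$spacing
  radii <- phantom_radii(params)

  ctr <- (shp + 1) / 2
  ax <- lapply(1:3, function(i) ((seq_len(shp[i]) - ctr[i]) * sp[i])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  dist_ctr <- sqrt(d2)

  class_map <- array(0L, shp)  # 0 background, 1 CSF, 2 WM, 3 GM
  class_map[dist_ctr <= radii["gm"]] <- 3L
  class_map[dist_ctr <= radii["wm"]] <- 2L
  class_map[dist_ctr <= radii["ventricle"]] <- 1L

  lookup <- function(means) {
    out <- array(0, shp)
    out[class_map == 1L] <- means[["csf"]]
    out[class_map == 2L] <- means[["wm"]]
    out[class_map == 3L] <- means[["gm"]]
    out
  }
  t1_mean <- lookup(as.list(params$t1_means))
  flair_mean <- lookup(as.list(params$flair_means))

  # lesions: spheres fully inside the WM shell, non-overlapping
  truth <- array(0, shp)
  lesion_log <- NULL
  n_les <- if (healthy) 0L else params$n_lesions
  if (n_les > 0L) {
    rr <- params$lesion_radius_range
    margin <- max(sp) / 2
    for (k in seq_len(n_les)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        r <- runif(1, rr[1], rr[2])
        lo <- radii["ventricle"] + r + margin
        hi <- radii["wm"] - r - margin
        if (lo >= hi)
          stop("lesions cannot be placed inside the WM shell; ",
               "reduce lesion radius or enlarge the phantom")
        u <- runif(1, lo, hi)
        dirv <- rnorm(3)
        dirv <- dirv / sqrt(sum(dirv^2))
        cmm <- u * dirv  # centre relative to volume centre, mm
        cvox <- cmm / sp + ctr
        axl <- lapply(1:3, function(i) ((seq_len(shp[i]) - cvox[i]) * sp[i])^2)
        ball <- outer(outer(axl[[1]], axl[[2]], "+"), axl[[3]], "+") <= r^2
        if (!any(ball & truth > 0)) {
          truth[ball] <- 1
          flair_mean[ball] <- flair_mean[ball] + params$lesion_flair_contrast
          t1_mean[ball] <- t1_mean[ball] + params$lesion_t1_contrast
          lesion_log <- rbind(lesion_log,
                              data.frame(cx = cvox[1], cy = cvox[2],
                                         cz = cvox[3], r_mm = r))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("lesions cannot be placed without overlap; ",
                        "reduce n_lesions or lesion radius")
    }
  }

  # benign periventricular bands/caps in healthy subjects
  if (healthy && params$band_cap_intensity != 0) {
    band <- class_map == 2L &
      dist_ctr <= radii["ventricle"] + 2 * max(sp)
    flair_mean[band] <- flair_mean[band] + params$band_cap_intensity
  }

  if (params$pv_smoothing_sigma > 0) {
    t1_mean <- gaussian_smooth3(t1_mean, params$pv_smoothing_sigma, sp)
    flair_mean <- gaussian_smooth3(flair_mean, params$pv_smoothing_sigma, sp)
  }

  head <- class_map > 0L
  sd_map <- function(sds) {
    out <- array(0, shp)
    out[class_map == 1L] <- sds[["csf"]]
    out[class_map == 2L] <- sds[["wm"]]
    out[class_map == 3L] <- sds[["gm"]]
    out
  }
  nhead <- sum(head)
  t1 <- t1_mean
  flair <- flair_mean
  t1[head] <- t1[head] + sd_map(as.list(params$t1_sds))[head] * rnorm(nhead) +
    params$noise_sd * rnorm(nhead)
  flair[head] <- flair[head] + sd_map(as.list(params$flair_sds))[head] * rnorm(nhead) +
    params$noise_sd * rnorm(nhead)
  # keep head voxels strictly positive (zero encodes background throughout)
  t1[head] <- pmax(t1[head], 1e-4)
  flair[head] <- pmax(flair[head], 1e-4)
  t1[!head] <- 0
  flair[!head] <- 0

  wm_prob <- array(0, shp); wm_prob[class_map == 2L] <- 1
  gm_prob <- array(0, shp); gm_prob[class_map == 3L] <- 1
  if (any(truth > 0)) {  # imperfect tissue segmentation inside lesions
    wm_prob[truth > 0] <- 0.6
    gm_prob[truth > 0] <- 0.1
  }
  vent <- array(0, shp); vent[class_map == 1L] <- 1

  vent_vg <- volume_grid(vent, sp)
  dvent <- mask_distance(vent_vg)
  atlas <- exp(-dvent / 5)
  atlas[vent > 0] <- 0
  atlas[!head] <- 0

  out <- subject_bundle(
    t1 = volume_grid(t1, sp),
    flair = volume_grid(flair, sp),
    wm_prob = volume_grid(wm_prob, sp),
    gm_prob = volume_grid(gm_prob, sp),
    ventricle_mask = vent_vg,
    atlas = volume_grid(atlas, sp),
    lesion_truth = volume_grid(truth, sp))
  attr(out, "lesions") <- lesion_log  # centres (voxel coords) and radii (mm)
  out
}

#' Generate a cohort of phantom subjects
#'
#' Subject seeds are derived deterministically from the master seed in
#' `params$seed`, so identical `(params, n, healthy)` give bit-identical
#' cohorts.
#'
#' @param n number of subjects (>= 1).
#' @param params a [phantom_params()]; `params$seed` is the master seed.
#' @param healthy logical; healthy subjects carry no lesions but gain the
#'   periventricular band/cap brightening.
#' @return a list of [subject_bundle()]s.
#' @export
generate_cohort <- function(n, params = phantom_params(), healthy = FALSE) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- derive_seed(params$seed, i)
    generate_subject(p, healthy = healthy)
  })
}

#' Average a cohort's reference lesion masks into a probabilistic atlas
#'
#' Voxel-wise mean of the available `lesion_truth` masks. When every mask is
#' empty (an all-healthy cohort), the analytic periventricular prior
#' `exp(-d / 5 mm)` of ventricle distance is returned instead, mimicking the
#' periventricular predominance of WMH of presumed vascular origin.
#'
#' @param cohort list of [subject_bundle()]s sharing one lattice.
#' @return a [volume_grid()] with values in `[0, 1]`.
#' @export
generate_atlas <- function(cohort) {
  if (length(cohort) == 0L) stop("empty cohort")
  ref <- cohort[[1L]]
  for (s in cohort) stopifnot_lattice(ref$t1, s$t1, what = "cohort subjects")
  masks <- lapply(cohort, function(s) s$lesion_truth)
  masks <- Filter(Negate(is.null), masks)
  if (length(masks) > 0L && any(vapply(masks, function(m) sum(m$data), 0) > 0)) {
    acc <- Reduce(`+`, lapply(masks, function(m) m$data)) / length(masks)
    return(volume_grid(pmin(pmax(acc, 0), 1), ref$t1$spacing))
  }
  dvent <- mask_distance(ref$ventricle_mask)
  atlas <- exp(-dvent / 5)
  atlas[ref$ventricle_mask$data > 0] <- 0
  atlas[ref$t1$data == 0] <- 0
  volume_grid(atlas, ref$t1$spacing)
}
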