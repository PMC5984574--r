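#' Pipeline configuration
#'
#' One object carrying every stage default: synthesis bank (`m`, `t_max`,
#' `h`, `a`, `pv_radius_mm`), GMM bank (`b`, `tol`, `max_iter`,
#' `sigma_floor`), fusion (`nu_wm`, `nu_gm`, `n_samples`, `svm_tolerance`,
#' `gamma`), the CRF parameter block, the phantom parameter block, the master
#' seed (fanned out deterministically to the per-stage seeds) and whether
#' bundles are normalised on entry. Serialisable with [config_write()] /
#' [config_read()].
#'
#' @param m,t_max,h,a synthesis-bank parameters; see [fit_model_bank()].
#' @param b,tol,max_iter,sigma_floor GMM-bank parameters; see
#'   [fit_gmm_bank()].
#' @param nu_wm,nu_gm,n_samples,svm_tolerance,gamma fusion parameters; see
#'   [train_fusion()].
#' @param pv_radius_mm periventricular capping radius in mm.
#' @param crf a [crf_params()].
#' @param phantom a [phantom_params()].
#' @param seed master integer seed.
#' @param normalise normalise bundles on entry to training / segmentation.
#' @param lflair_variant `"neglog"` or `"density"`; see [compute_lflair()].
#' @param verbose log stage progress and input checksums.
#' @return an object of class `"wmh_control"`.
#' @export
wmh_control <- function(m = 100L, t_max = 1500, h = 50, a = 5L,
                        b = 5L, tol = 1e-6, max_iter = 200L, sigma_floor = 1,
                        nu_wm = 0.05, nu_gm = 0.003, n_samples = 50000L,
                        svm_tolerance = 1e-5, gamma = NULL,
                        pv_radius_mm = 15,
                        crf = crf_params(), phantom = phantom_params(),
                        seed = 1L, normalise = TRUE,
                        lflair_variant = "neglog", verbose = FALSE) {
  structure(list(m = as.integer(m), t_max = t_max, h = h, a = as.integer(a),
                 b = as.integer(b), tol = tol, max_iter = as.integer(max_iter),
                 sigma_floor = sigma_floor, nu_wm = nu_wm, nu_gm = nu_gm,
                 n_samples = as.integer(n_samples),
                 svm_tolerance = svm_tolerance, gamma = gamma,
                 pv_radius_mm = pv_radius_mm, crf = crf, phantom = phantom,
                 seed = as.integer(seed), normalise = isTRUE(normalise),
                 lflair_variant = lflair_variant,
                 verbose = isTRUE(verbose)), class = "wmh_control")
}

#' Write / read a pipeline configuration
#'
#' The configuration round-trips through a single YAML file; unknown keys are
#' rejected on read.
#'
#' @param control a [wmh_control()].
#' @param path file path.
#' @return `config_read()` returns a [wmh_control()]; `config_write()` the
#'   path, invisibly.
#' @export
config_write <- function(control, path) {
  stopifnot(inherits(control, "wmh_control"))
  x <- unclass(control)
  x$crf <- unclass(x$crf)
  x$phantom <- lapply(unclass(x$phantom), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(wmh_control))
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  if (!is.null(x$crf)) x$crf <- do.call(crf_params, x$crf)
  if (!is.null(x$phantom)) {
    ph <- x$phantom
    for (f in c("t1_means", "t1_sds", "flair_means", "flair_sds"))
      if (!is.null(ph[[f]])) ph[[f]] <- unlist(ph[[f]])
    x$phantom <- do.call(phantom_params, ph)
  }
  do.call(wmh_control, x)
}

#' Train the full segmentation model
#'
#' Runs normalisation, the synthesis model bank with its transfer function
#' and periventricular cap, the per-voxel GMM bank, the per-subject `L^SYN` /
#' `L^FLAIR` maps, and the per-tissue one-class fusion classifiers on a
#' training cohort (healthy, or with reference lesion masks that are then
#' dilated and excluded from fusion training). The CRF unary temperature is
#' set to the 90th percentile of the positive training scores.
#'
#' @param cohort list of [subject_bundle()]s.
#' @param control a [wmh_control()].
#' @return an object of class `"wmh_model"` bundling the synthesis bank, GMM
#'   bank, fusion model, atlas and control; use [predict.wmh_model()] or
#'   [segment_subject()] to segment new subjects.
#' @export
wmh_train <- function(cohort, control = wmh_control()) {
  stopifnot(inherits(control, "wmh_control"))
  verbose <- control$verbose
  cohort <- lapply(cohort, check_bundle)
  if (control$normalise) {
    log_stage(verbose, "normalising %d training subjects", length(cohort))
    cohort <- lapply(cohort, normalise_bundle)
  }
  atlas <- generate_atlas(cohort)
  log_stage(verbose, "atlas %s", vol_checksum(atlas))

  bank <- fit_model_bank(cohort, m = control$m, t_max = control$t_max,
                         h = control$h, a = control$a,
                         pv_radius_mm = control$pv_radius_mm,
                         verbose = verbose)
  gmm <- fit_gmm_bank(lapply(cohort, `[[`, "flair"), b = control$b,
                      tol = control$tol, max_iter = control$max_iter,
                      sigma_floor = control$sigma_floor, verbose = verbose)

  log_stage(verbose, "computing training feature maps")
  feats <- lapply(cohort, function(s) {
    synth <- synthesise(s$t1, bank)
    lsyn <- compute_lsyn(s$flair, synth)
    lflair <- compute_lflair(s$flair, gmm, variant = control$lflair_variant)
    assemble_features(lsyn, lflair, atlas, s$wm_prob, s$gm_prob)
  })
  truths <- lapply(cohort, `[[`, "lesion_truth")
  have_lesions <- any(vapply(truths, function(m)
    !is.null(m) && sum(m$data) > 0, TRUE))
  fusion <- train_fusion(feats,
                         lesion_exclusion_masks = if (have_lesions) truths,
                         nu_wm = control$nu_wm, nu_gm = control$nu_gm,
                         n_samples = control$n_samples,
                         seed = derive_seed(control$seed, 101L),
                         gamma = control$gamma,
                         tolerance = control$svm_tolerance)

  log_stage(verbose, "calibrating unary temperature")
  # scores below 1e-3 are decision-value noise from the QP termination
  # tolerance (the one-class surface is numerically flat near the training
  # cloud), not meaningful outlier distances; they must not drag the
  # temperature down
  pos <- unlist(lapply(feats, function(f) {
    s <- score_voxels(f, fusion)$data
    s[s > 1e-3]
  }))
  tau <- if (length(pos)) quantile(pos, 0.9, names = FALSE) else 1
  crf <- control$crf
  if (is.null(crf$tau)) crf$tau <- tau

  structure(list(synthesis = bank, gmm = gmm, fusion = fusion, atlas = atlas,
                 crf = crf, control = control, n_train = length(cohort)),
            class = "wmh_model")
}

#' @export
print.wmh_model <- function(x, ...) {
  cat(sprintf(paste0("<wmh_model> trained on %d subjects; %d voxel synthesis ",
                     "curves, %d voxel mixtures,\n  one-class SVMs ",
                     "(nu WM=%g, GM=%g), CRF (w2=%g, sigma_gamma=%g, tau=%.3g)\n"),
              x$n_train, ncol(x$synthesis$curves), ncol(x$gmm$params),
              x$fusion$wm$nu, x$fusion$gm$nu, x$crf$w2, x$crf$sigma_gamma,
              x$crf$tau))
  invisible(x)
}

#' @export
summary.wmh_model <- function(object, ...) {
  cat("Unsupervised FLAIR lesion segmentation model\n")
  print(object)
  cat("Synthesis bank: "); print(object$synthesis)
  cat("GMM bank:       "); print(object$gmm)
  cat("Fusion:         "); print(object$fusion)
  invisible(object)
}

#' Segment one subject
#'
#' Applies the trained model: normalisation (if enabled), pseudo-healthy
#' synthesis, `L^SYN`, `L^FLAIR`, one-class scoring and CRF binarisation.
#'
#' @param model a `"wmh_model"`.
#' @param subject a [subject_bundle()] on the model lattice.
#' @param control optional [wmh_control()] override (default: the model's).
#' @return an object of class `"wmh_segmentation"`: `mask`, `lsyn`,
#'   `lflair`, `lsvm` ([volume_grid()]s), plus `lesion_ml`.
#' @export
segment_subject <- function(model, subject, control = model$control) {
  stopifnot(inherits(model, "wmh_model"))
  subject <- check_bundle(subject)
  if (!identical(dim(subject$t1$data), model$synthesis$shape))
    stop("subject does not share the model lattice")
  if (control$normalise) subject <- normalise_bundle(subject)
  synth <- synthesise(subject$t1, model$synthesis)
  lsyn <- compute_lsyn(subject$flair, synth)
  lflair <- compute_lflair(subject$flair, model$gmm,
                           variant = control$lflair_variant)
  feats <- assemble_features(lsyn, lflair, model$atlas,
                             subject$wm_prob, subject$gm_prob)
  lsvm <- score_voxels(feats, model$fusion)
  unary <- build_unary(lsvm, model$crf$tau, model$crf$eps)
  mask <- meanfield_crf(unary, subject$flair, model$crf)
  structure(list(mask = mask, lsyn = lsyn, lflair = lflair, lsvm = lsvm,
                 synthetic = synth,
                 lesion_ml = sum(mask$data) * prod(mask$spacing) / 1000),
            class = "wmh_segmentation")
}

#' @export
print.wmh_segmentation <- function(x, ...) {
  cat(sprintf("<wmh_segmentation> %g voxels segmented (%.3f ml)\n",
              sum(x$mask$data), x$lesion_ml))
  invisible(x)
}

#' @param object a `"wmh_model"`.
#' @param newdata a [subject_bundle()] to segment.
#' @param ... unused.
#' @rdname segment_subject
#' @export
predict.wmh_model <- function(object, newdata, ...) {
  segment_subject(object, newdata)
}

# synthetic clinical rating: a monotone 0-6 discretisation of lesion load,
# standing in for combined periventricular + deep WMH scores on phantoms
synthetic_fazekas <- function(truth_ml) {
  breaks <- c(-Inf, 0.05, 0.2, 0.5, 1, 2, 4, Inf)
  as.integer(cut(truth_ml, breaks)) - 1L
}

#' Evaluate segmentations against reference masks
#'
#' Per-subject overlap and surface metrics plus the groupwise statistics:
#' ICC(A,1), Bland-Altman agreement, rank correlation with (synthetic)
#' clinical scores, and lesion- and subject-binned Dice.
#'
#' @param pairs list of [seg_pair()]s.
#' @param icv intracranial volumes in ml (default: brain volume is not
#'   available from a pair, so callers supply it).
#' @param fazekas optional integer ratings in `[0, 6]` per subject.
#' @return list with `per_subject` (data frame), `icc`, `agreement`,
#'   `fazekas_rho`, `dsc_by_lesion`, `dsc_by_subject`.
#' @export
evaluate_cohort <- function(pairs, icv, fazekas = NULL) {
  vol_a <- vapply(pairs, function(p) sum(p$pred$data) * p$voxel_ml, 0)
  vol_t <- vapply(pairs, function(p) sum(p$truth$data) * p$voxel_ml, 0)
  per <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    om <- overlap_metrics(pairs[[i]])
    sm <- surface_metrics(pairs[[i]])
    data.frame(subject = i, vol_pred_ml = vol_a[i], vol_truth_ml = vol_t[i],
               dsc = om$dsc, precision = om$precision, recall = om$recall,
               assd = sm$assd, hd = sm$hd)
  }))
  if (is.null(fazekas)) fazekas <- synthetic_fazekas(vol_t)
  agr <- if (length(pairs) >= 3 && isTRUE(var(vol_t / icv) > 0) &&
               isTRUE(var(vol_a / icv) > 0))
    agreement_stats(vol_a, vol_t, icv) else NULL
  list(per_subject = per,
       icc = if (length(pairs) >= 3) icc_a1(vol_a, vol_t) else NA_real_,
       agreement = agr,
       fazekas_rho = fazekas_correlation(vol_a, icv, fazekas),
       dsc_by_lesion = volume_binned_dsc(pairs, "lesion"),
       dsc_by_subject = volume_binned_dsc(pairs, "subject"))
}

#' End-to-end phantom demonstration
#'
#' Generates a healthy training cohort and a lesioned test cohort, trains the
#' model, segments every test subject plus a set of healthy subjects (to
#' measure the false-positive volume), evaluates, and writes a per-subject
#' CSV and a JSON summary.
#'
#' @param seed master seed.
#' @param n_train,n_test,n_healthy_test cohort sizes.
#' @param out_dir output directory (default: a fresh temporary directory).
#' @param quick use a 32-voxel cube instead of the default 48 (faster,
#'   coarser).
#' @param control optional [wmh_control()]; its phantom block and seed are
#'   overridden by the arguments above.
#' @return an object of class `"wmh_report"`: the [evaluate_cohort()] output
#'   plus `healthy_fp_fraction`, `mean_dsc`, paths, and timing.
#' @export
run_demo <- function(seed = 1L, n_train = 20L, n_test = 10L,
                     n_healthy_test = 3L, out_dir = NULL, quick = FALSE,
                     control = wmh_control()) {
  t0 <- Sys.time()
  if (is.null(out_dir)) out_dir <- tempfile("wmh_demo_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  control$seed <- as.integer(seed)
  if (quick) {
    control$phantom$shape <- c(32L, 32L, 32L)
    control$phantom$lesion_radius_range <- c(1.5, 2.5)
  }
  ph <- control$phantom

  ph_train <- ph; ph_train$seed <- derive_seed(seed, 1L)
  train <- generate_cohort(n_train, ph_train, healthy = TRUE)
  ph_test <- ph; ph_test$seed <- derive_seed(seed, 2L)
  test <- generate_cohort(n_test, ph_test, healthy = FALSE)
  ph_h <- ph; ph_h$seed <- derive_seed(seed, 3L)
  healthy_test <- if (n_healthy_test > 0)
    generate_cohort(n_healthy_test, ph_h, healthy = TRUE) else list()

  model <- wmh_train(train, control)

  segs <- lapply(test, function(s) segment_subject(model, s))
  pairs <- lapply(seq_along(test), function(i)
    seg_pair(segs[[i]]$mask, test[[i]]$lesion_truth))
  brain_vox <- vapply(test, function(s) sum(s$t1$data > 0), 0)
  icv <- brain_vox * prod(ph$spacing) / 1000

  report <- evaluate_cohort(pairs, icv)
  report$mean_dsc <- mean(report$per_subject$dsc)

  fp <- vapply(healthy_test, function(s) {
    seg <- segment_subject(model, s)
    sum(seg$mask$data) / sum(s$t1$data > 0)
  }, 0)
  report$healthy_fp_fraction <- if (length(fp)) mean(fp) else NA_real_

  csv_path <- file.path(out_dir, "per_subject.csv")
  write.csv(report$per_subject, csv_path, row.names = FALSE)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    mean_dsc = report$mean_dsc, icc = report$icc,
    fazekas_rho = report$fazekas_rho,
    healthy_fp_fraction = report$healthy_fp_fraction,
    agreement = report$agreement,
    dsc_by_lesion = report$dsc_by_lesion,
    dsc_by_subject = report$dsc_by_subject,
    seed = seed, n_train = n_train, n_test = n_test,
    shape = ph$shape), summary_path, auto_unbox = TRUE, digits = NA,
    na = "null")
  report$paths <- c(per_subject = csv_path, summary = summary_path)
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$model <- model
  class(report) <- "wmh_report"
  report
}

#' @export
print.wmh_report <- function(x, ...) {
  cat(sprintf(paste0("<wmh_report> %d test subjects: mean DSC %.3f, ",
                     "ICC %.3f, Fazekas rho %.3f\n  healthy FP fraction %s, ",
                     "elapsed %.1f s\n"),
              nrow(x$per_subject), x$mean_dsc, x$icc, x$fazekas_rho,
              ifelse(is.na(x$healthy_fp_fraction), "NA",
                     sprintf("%.4f", x$healthy_fp_fraction)),
              x$elapsed_s))
  invisible(x)
}
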