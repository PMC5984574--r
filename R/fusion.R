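#' Assemble per-voxel fusion feature vectors
#'
#' Per brain voxel, the 3-vector `[L^SYN, L^FLAIR, atlas]`. Each voxel is
#' routed to the tissue class with the greater probability (WM or GM); voxels
#' with `wm_prob + gm_prob < 0.5` (CSF, background) are excluded — no
#' classifier is trained for them.
#'
#' @param lsyn,lflair,atlas feature [volume_grid()]s on one lattice.
#' @param wm_prob,gm_prob tissue probability maps.
#' @return an object of class `"feature_set"`: `features` (n x 3 matrix),
#'   `idx` (linear voxel indices), `route` (factor `WM`/`GM`), `shape`,
#'   `spacing`.
#' @export
assemble_features <- function(lsyn, lflair, atlas, wm_prob, gm_prob) {
  stopifnot_lattice(lsyn, lflair, atlas, wm_prob, gm_prob)
  keep <- which(wm_prob$data + gm_prob$data >= 0.5)
  route <- factor(ifelse(wm_prob$data[keep] > gm_prob$data[keep], "WM", "GM"),
                  levels = c("WM", "GM"))
  features <- cbind(lsyn = lsyn$data[keep], lflair = lflair$data[keep],
                    atlas = atlas$data[keep])
  if (length(keep) && !all(is.finite(features))) stop("non-finite feature value")
  structure(list(features = features, idx = keep, route = route,
                 shape = dim(lsyn$data), spacing = lsyn$spacing),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d voxels (%d WM, %d GM) of %d\n",
              nrow(x$features), sum(x$route == "WM"), sum(x$route == "GM"),
              prod(x$shape)))
  invisible(x)
}

scale_features <- function(x, center, scale) {
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}

#' Train the per-tissue one-class fusion classifiers
#'
#' Pools feature vectors across training subjects per tissue route, removes
#' voxels under (one-voxel-dilated) lesion-exclusion masks when provided,
#' draws `n_samples` vectors uniformly at random per route, scales each
#' feature dimension by the sample median/IQR, and trains a one-class SVM
#' with a radial-basis kernel and training outlier fraction `nu` (5% for WM,
#' 0.3% for GM by default). The RBF width defaults to the reciprocal of
#' (feature dimension x mean per-dimension variance of the scaled sample).
#' The quadratic-programme termination tolerance is kept tight (1e-5) so the
#' nu-property — at most a fraction nu of training points outside the
#' boundary — holds at small nu.
#'
#' @param train_features list of [assemble_features()] results, one per
#'   training subject (a single `"feature_set"` is also accepted).
#' @param lesion_exclusion_masks optional list of binary [volume_grid()]s
#'   (reference lesions); dilated by one voxel and masked out of training.
#' @param nu_wm,nu_gm training outlier fractions.
#' @param n_samples training points drawn per route (default 50000).
#' @param seed integer seed for the sampling.
#' @param gamma optional RBF width override (shared by both classifiers).
#' @param tolerance SVM termination tolerance.
#' @return an object of class `"fusion_model"`.
#' @importFrom e1071 svm
#' @export
train_fusion <- function(train_features, lesion_exclusion_masks = NULL,
                         nu_wm = 0.05, nu_gm = 0.003, n_samples = 50000L,
                         seed = 1L, gamma = NULL, tolerance = 1e-5) {
  if (inherits(train_features, "feature_set"))
    train_features <- list(train_features)
  pools <- list(WM = NULL, GM = NULL)
  for (i in seq_along(train_features)) {
    fs <- train_features[[i]]
    keep <- rep(TRUE, nrow(fs$features))
    if (!is.null(lesion_exclusion_masks) &&
        !is.null(lesion_exclusion_masks[[i]]) &&
        sum(lesion_exclusion_masks[[i]]$data) > 0) {
      excl <- dilate_mask3(lesion_exclusion_masks[[i]]$data, 1L)
      keep <- !excl[fs$idx]
    }
    for (r in c("WM", "GM")) {
      sel <- keep & fs$route == r
      pools[[r]] <- rbind(pools[[r]], fs$features[sel, , drop = FALSE])
    }
  }
  fit_route <- function(x, nu, route_k) {
    if (nrow(x) < n_samples / 10)
      stop(sprintf("too few pooled features for route %d: %d (need >= %d)",
                   route_k, nrow(x), ceiling(n_samples / 10)))
    set.seed(derive_seed(seed, route_k))
    take <- if (nrow(x) >= n_samples) sample.int(nrow(x), n_samples)
            else sample.int(nrow(x), n_samples, replace = TRUE)
    s <- x[take, , drop = FALSE]
    center <- apply(s, 2L, median)
    scl <- apply(s, 2L, function(v) max(stats::IQR(v), 1e-8))
    z <- scale_features(s, center, scl)
    g <- if (is.null(gamma)) 1 / (ncol(z) * max(mean(apply(z, 2L, var)), 1e-8))
         else gamma
    svm <- e1071::svm(z, type = "one-classification", kernel = "radial",
                      nu = nu, gamma = g, scale = FALSE,
                      tolerance = tolerance)
    list(svm = svm, center = center, scale = scl, nu = nu, gamma = g,
         sample_idx = take)
  }
  structure(list(wm = fit_route(pools$WM, nu_wm, 1L),
                 gm = fit_route(pools$GM, nu_gm, 2L),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 tolerance = tolerance), class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(paste0("<fusion_model> one-class RBF SVMs: WM (nu=%g, %d SV), ",
                     "GM (nu=%g, %d SV), %d training points each\n"),
              x$wm$nu, x$wm$svm$tot.nSV, x$gm$nu, x$gm$svm$tot.nSV,
              x$n_samples))
  invisible(x)
}

# decision values for a scaled-route predictor; positive inside the boundary
route_decision <- function(route_model, x) {
  z <- scale_features(x, route_model$center, route_model$scale)
  p <- predict(route_model$svm, z, decision.values = TRUE)
  as.numeric(attr(p, "decision.values"))
}

#' Score voxels with the fusion model
#'
#' Each voxel is scored by its route's one-class classifier: inliers score 0;
#' outliers score their (positive) distance beyond the decision boundary.
#' Excluded voxels score 0. The assembled map is `L^SVM`.
#'
#' @param features a `"feature_set"` from [assemble_features()].
#' @param model a `"fusion_model"` from [train_fusion()].
#' @return the `L^SVM` score [volume_grid()], nonnegative everywhere.
#' @export
score_voxels <- function(features, model) {
  stopifnot(inherits(features, "feature_set"),
            inherits(model, "fusion_model"))
  out <- array(0, features$shape)
  for (r in c("WM", "GM")) {
    sel <- features$route == r
    if (!any(sel)) next
    rm_ <- if (r == "WM") model$wm else model$gm
    dv <- route_decision(rm_, features$features[sel, , drop = FALSE])
    out[features$idx[sel]] <- pmax(0, -dv)
  }
  volume_grid(out, features$spacing)
}
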