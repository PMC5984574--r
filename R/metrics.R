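#' Pair a computed and a reference segmentation
#'
#' @param pred,truth binary [volume_grid()]s on one lattice.
#' @return an object of class `"seg_pair"`; `voxel_ml` is the voxel volume in
#'   millilitres derived from the spacing.
#' @export
seg_pair <- function(pred, truth) {
  stopifnot_lattice(pred, truth)
  if (!all(pred$data %in% c(0, 1)) || !all(truth$data %in% c(0, 1)))
    stop("segmentation masks must be 0/1")
  structure(list(pred = pred, truth = truth,
                 voxel_ml = prod(pred$spacing) / 1000),
            class = "seg_pair")
}

#' Overlap metrics: Dice, precision, recall
#'
#' `DSC = 2|A n B| / (|A| + |B|)`, `precision = |A n B| / |A|`,
#' `recall = |A n B| / |B|` for computed mask `A` and reference `B`.
#' Conventions for empty masks: both empty gives 1 for all three (perfect
#' agreement); exactly one empty gives DSC 0 and `NA` for the ratio whose
#' denominator is empty.
#'
#' @param pair a [seg_pair()].
#' @return named list `dsc`, `precision`, `recall`.
#' @export
overlap_metrics <- function(pair) {
  a <- pair$pred$data > 0
  b <- pair$truth$data > 0
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0)
    return(list(dsc = 1, precision = 1, recall = 1))
  inter <- sum(a & b)
  list(dsc = 2 * inter / (na + nb),
       precision = if (na > 0) inter / na else NA_real_,
       recall = if (nb > 0) inter / nb else NA_real_)
}

# boundary voxels: in the mask with at least one 6-neighbour outside it
# (volume edges count as outside); returns their coordinates in mm
surface_points <- function(mask, spacing) {
  m <- mask > 0
  d <- dim(m)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    lo <- m; hi <- m
    idx_lo <- c(1L, seq_len(d[ax] - 1L))
    idx_hi <- c(seq_len(d[ax] - 1L) + 1L, d[ax])
    if (ax == 1) { lo <- m[idx_lo, , , drop = FALSE]; hi <- m[idx_hi, , , drop = FALSE]
      lo[1, , ] <- FALSE; hi[d[1], , ] <- FALSE }
    if (ax == 2) { lo <- m[, idx_lo, , drop = FALSE]; hi <- m[, idx_hi, , drop = FALSE]
      lo[, 1, ] <- FALSE; hi[, d[2], ] <- FALSE }
    if (ax == 3) { lo <- m[, , idx_lo, drop = FALSE]; hi <- m[, , idx_hi, drop = FALSE]
      lo[, , 1] <- FALSE; hi[, , d[3]] <- FALSE }
    interior <- interior & lo & hi
  }
  surf <- m & !interior
  w <- which(surf, arr.ind = TRUE)
  sweep(w, 2L, spacing, "*")
}

#' Surface distance metrics: ASSD and Hausdorff distance
#'
#' Surfaces are the 6-connected boundary voxels of each mask; distances are
#' Euclidean between voxel centres in mm. ASSD is the mean of the two
#' directed mean minimum distances; HD the maximum over both directed
#' maximum minimum distances.
#'
#' @param pair a [seg_pair()].
#' @return named list `assd`, `hd` (mm); both `NA` when either mask is empty
#'   (undefined, reported as missing).
#' @export
surface_metrics <- function(pair) {
  if (sum(pair$pred$data) == 0 || sum(pair$truth$data) == 0)
    return(list(assd = NA_real_, hd = NA_real_))
  sp <- pair$pred$spacing
  A <- surface_points(pair$pred$data, sp)
  B <- surface_points(pair$truth$data, sp)
  dab <- cpp_min_dists(A, B)
  dba <- cpp_min_dists(B, A)
  list(assd = (mean(dab) + mean(dba)) / 2,
       hd = max(max(dab), max(dba)))
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way model, absolute agreement, single measurement (McGraw & Wong),
#' from the two-rater ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with `k = 2` raters.
#' Sensitive to fixed bias, unlike consistency ICCs.
#'
#' @param volumes_a,volumes_t numeric vectors (computed / reference), equal
#'   length >= 3.
#' @return scalar in `[-1, 1]`.
#' @export
icc_a1 <- function(volumes_a, volumes_t) {
  n <- length(volumes_a)
  if (n != length(volumes_t)) stop("volume vectors differ in length")
  if (n < 3L) stop("at least 3 subjects are required")
  k <- 2
  Y <- cbind(volumes_a, volumes_t)
  grand <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((Y - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Connected lesion components of a reference mask
#'
#' @param mask binary [volume_grid()].
#' @param connectivity 26 (default) or 6.
#' @return integer array of component labels (0 = background).
#' @export
lesion_components <- function(mask, connectivity = 26L) {
  lab <- cpp_components(dim(mask$data), as.logical(mask$data != 0),
                        as.integer(connectivity))
  array(lab, dim(mask$data))
}

#' Volume-binned Dice coefficients
#'
#' `mode = "lesion"`: reference masks are split into 26-connected components;
#' each component's DSC is computed inside its axis-aligned bounding box and
#' the components are binned by volume into very small (< 0.01 ml), small
#' (0.01-0.1), medium (0.1-1), large (1-10) and very large (>= 10 ml).
#' `mode = "subject"`: whole-subject DSC binned by total reference volume
#' into < 5, 5-10, 10-15 and > 15 ml.
#'
#' @param pairs list of [seg_pair()]s (one per subject).
#' @param mode `"lesion"` or `"subject"`.
#' @return data frame with columns `bin`, `n`, `mean_dsc`; empty bins are
#'   reported with `n = 0` and `mean_dsc = NA`.
#' @export
volume_binned_dsc <- function(pairs, mode = c("lesion", "subject")) {
  mode <- match.arg(mode)
  if (inherits(pairs, "seg_pair")) pairs <- list(pairs)
  if (mode == "lesion") {
    breaks <- c(0, 0.01, 0.1, 1, 10, Inf)
    labels <- c("<0.01 ml", "0.01-0.1 ml", "0.1-1 ml", "1-10 ml", ">=10 ml")
    vols <- numeric(0); dscs <- numeric(0)
    for (p in pairs) {
      lab <- lesion_components(p$truth)
      for (comp in setdiff(unique(as.vector(lab)), 0L)) {
        sel <- lab == comp
        w <- which(sel, arr.ind = TRUE)
        rng <- apply(w, 2L, range)
        bb <- lapply(1:3, function(i) rng[1, i]:rng[2, i])
        pred_bb <- p$pred$data[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
        truth_bb <- sel[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
        inter <- sum(pred_bb > 0 & truth_bb)
        dscs <- c(dscs, 2 * inter / (sum(pred_bb > 0) + sum(truth_bb)))
        vols <- c(vols, sum(sel) * p$voxel_ml)
      }
    }
  } else {
    breaks <- c(0, 5, 10, 15, Inf)
    labels <- c("<5 ml", "5-10 ml", "10-15 ml", ">15 ml")
    vols <- vapply(pairs, function(p) sum(p$truth$data) * p$voxel_ml, 0)
    dscs <- vapply(pairs, function(p) overlap_metrics(p)$dsc, 0)
  }
  bin <- cut(vols, breaks, labels = labels, right = FALSE,
             include.lowest = TRUE)
  out <- data.frame(bin = labels,
                    n = as.integer(table(factor(bin, levels = labels))),
                    mean_dsc = NA_real_)
  for (i in seq_along(labels))
    if (out$n[i] > 0) out$mean_dsc[i] <- mean(dscs[bin == labels[i]])
  out
}

#' Bland-Altman agreement statistics
#'
#' Works on intracranial-volume-normalised lesion volumes
#' `v = |V| / |V_ic|`: the least-squares best-fit line of computed on
#' reference, its `r^2` (squared Pearson correlation) and SSE; the ratio
#' differences `d = (v_a - v_t) / (0.5 (v_a + v_t))`; the reproducibility
#' coefficient `RPC = 1.96 SD(d)`; the coefficient of variation
#' `CV = 100 SD(d) / mean(0.5 (v_a + v_t))`; and `mean(d)` with the p-value
#' of a two-sided one-sample Wilcoxon signed-rank test of zero location
#' (lesion volumes are typically non-normal).
#'
#' @param volumes_a,volumes_t computed / reference volumes.
#' @param icv intracranial volumes (> 0), same length.
#' @return named list `slope`, `intercept`, `r2`, `sse`, `rpc`, `cv`,
#'   `mean_diff`, `p_value`.
#' @export
agreement_stats <- function(volumes_a, volumes_t, icv) {
  n <- length(volumes_a)
  stopifnot(n == length(volumes_t), n == length(icv), all(icv > 0))
  a <- volumes_a / icv
  t <- volumes_t / icv
  if (var(t) == 0 || var(a) == 0)
    stop("zero-variance input: r^2 is undefined")
  fit <- stats::lm.fit(cbind(1, t), a)
  avg <- 0.5 * (a + t)
  d <- ifelse(avg > 0, (a - t) / avg, 0)
  p_val <- if (all(d == 0)) NA_real_ else
    suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided")$p.value)
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r2 = cor(a, t)^2,
       sse = sum(fit$residuals^2),
       rpc = 1.96 * sd(d),
       cv = 100 * sd(d) / mean(avg),
       mean_diff = mean(d),
       p_value = p_val)
}

#' Rank correlation with clinical lesion scores
#'
#' Spearman correlation (average ranks for ties) between
#' intracranial-volume-normalised segmentation volumes and a combined
#' periventricular + deep WMH rating in `[0, 6]`.
#'
#' @param volumes_a computed volumes.
#' @param icv intracranial volumes (> 0).
#' @param fazekas integer scores, each in `[0, 6]`.
#' @return Spearman's rho; `NA` when either variable has zero variance
#'   (undefined, reported as missing).
#' @export
fazekas_correlation <- function(volumes_a, icv, fazekas) {
  stopifnot(length(volumes_a) == length(icv),
            length(volumes_a) == length(fazekas), all(icv > 0))
  if (any(fazekas < 0 | fazekas > 6 | fazekas != round(fazekas)))
    stop("fazekas scores must be integers in [0, 6]")
  v <- volumes_a / icv
  if (length(v) < 2 || var(v) == 0 || var(fazekas) == 0) return(NA_real_)
  suppressWarnings(cor(v, fazekas, method = "spearman"))
}
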