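# feature volumes with controllable tissue routing
mk_feature_vols <- function(n_side = 16L, seed = 1L) {
  set.seed(seed)
  shp <- rep(n_side, 3L)
  n <- prod(shp)
  half <- array(rep(c(1, 0), each = n / 2), shp)
  list(lsyn = volume_grid(array(rnorm(n), shp)),
       lflair = volume_grid(array(abs(rnorm(n)), shp)),
       atlas = volume_grid(array(runif(n), shp)),
       wm = volume_grid(half),
       gm = volume_grid(1 - half))
}

test_that("features are routed to the dominant tissue and CSF is excluded", {
  wm <- volume_grid(array(c(0.9, 0.2, 0.4, 0.1), c(4, 1, 1)))
  gm <- volume_grid(array(c(0.05, 0.2, 0.5, 0.1), c(4, 1, 1)))
  z <- volume_grid(array(0, c(4, 1, 1)))
  fs <- assemble_features(z, z, z, wm, gm)
  expect_equal(fs$idx, c(1L, 3L))            # 0.2+0.2 and 0.1+0.1 excluded
  expect_equal(as.character(fs$route), c("WM", "GM"))
  expect_equal(nrow(fs$features), 2L)
})

test_that("one-class training is deterministic and honours its nu", {
  v <- mk_feature_vols(16L)
  fs <- assemble_features(v$lsyn, v$lflair, v$atlas, v$wm, v$gm)
  m1 <- train_fusion(fs, nu_wm = 0.05, nu_gm = 0.05, n_samples = 2000L,
                     seed = 4L)
  m2 <- train_fusion(fs, nu_wm = 0.05, nu_gm = 0.05, n_samples = 2000L,
                     seed = 4L)
  expect_identical(m1$wm$sample_idx, m2$wm$sample_idx)
  expect_identical(m1$wm$svm$rho, m2$wm$svm$rho)

  # nu-property at a moderate sample size
  v2 <- mk_feature_vols(32L, seed = 9L)
  fs2 <- assemble_features(v2$lsyn, v2$lflair, v2$atlas, v2$wm, v2$gm)
  m <- train_fusion(fs2, nu_wm = 0.05, nu_gm = 0.05, n_samples = 10000L,
                    seed = 2L)
  pool <- fs2$features[fs2$route == "WM", ][m$wm$sample_idx, ]
  frac <- mean(lesionsynth:::route_decision(m$wm, pool) < 0)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("duplicating every training point leaves the boundary essentially
           unchanged", {
  v <- mk_feature_vols(16L, seed = 3L)
  fs <- assemble_features(v$lsyn, v$lflair, v$atlas, v$wm, v$gm)
  dup <- fs
  dup$features <- rbind(fs$features, fs$features)
  dup$idx <- c(fs$idx, fs$idx)
  dup$route <- factor(c(as.character(fs$route), as.character(fs$route)),
                      levels = c("WM", "GM"))
  m1 <- train_fusion(fs, nu_wm = 0.1, nu_gm = 0.1, n_samples = 2000L, seed = 1L)
  m2 <- train_fusion(dup, nu_wm = 0.1, nu_gm = 0.1, n_samples = 2000L, seed = 1L)
  # median/IQR scaling is stable under duplication (the samples drawn from
  # the doubled pool differ, the distribution does not)
  expect_lt(max(abs(m1$wm$center - m2$wm$center)), 0.1)
  expect_lt(max(abs(m1$wm$scale / m2$wm$scale - 1)), 0.1)
  # decision values agree closely on a probe grid
  probe <- as.matrix(expand.grid(seq(-2, 2, 1), seq(-2, 2, 1), seq(0, 1, 0.5)))
  colnames(probe) <- colnames(fs$features)
  d1 <- lesionsynth:::route_decision(m1$wm, probe)
  d2 <- lesionsynth:::route_decision(m2$wm, probe)
  expect_gt(cor(d1, d2), 0.99)
  expect_gt(mean(sign(d1) == sign(d2)), 0.9)
})

test_that("scores are zero for inliers, positive far away, zero on excluded
           voxels", {
  set.seed(6)
  shp <- c(12L, 12L, 12L)
  n <- prod(shp)
  cloud <- function() volume_grid(array(rnorm(n, 0, 0.05), shp))
  wm <- volume_grid(array(1, shp))
  gm <- volume_grid(array(0, shp))
  gm$data[, , 1:2] <- 1; wm$data[, , 1:2] <- 0
  fs <- assemble_features(cloud(), cloud(), cloud(), wm, gm)
  m <- train_fusion(fs, nu_wm = 0.05, nu_gm = 0.05, n_samples = 1000L,
                    seed = 8L)
  # centroid of the tight training cloud sits (numerically) on or inside
  # the boundary: its outlier score is at noise scale
  centroid <- matrix(0, 1, 3, dimnames = list(NULL, colnames(fs$features)))
  dv_c <- lesionsynth:::route_decision(m$wm, centroid)
  expect_lt(max(0, -dv_c), 0.01)
  # a point 10 sample-SDs out is flagged by the decision sign and scores
  # strictly positive, far above the centroid
  far <- matrix(0.5, 1, 3, dimnames = list(NULL, colnames(fs$features)))
  dv_f <- lesionsynth:::route_decision(m$wm, far)
  expect_lt(dv_f, 0)
  expect_gt(-dv_f, 100 * max(0, -dv_c))

  # assembled map: nonnegative everywhere, zero on excluded voxels
  probe_vol <- cloud()
  probe_vol$data[3, 3, 6] <- 10   # one blatant outlier feature
  fs2 <- assemble_features(probe_vol, cloud(), cloud(), wm, gm)
  lsvm <- score_voxels(fs2, m)
  expect_true(all(lsvm$data >= 0))
  expect_gt(lsvm$data[3, 3, 6], 0)
  excluded <- array(TRUE, shp)
  excluded[fs2$idx] <- FALSE
  expect_true(all(lsvm$data[excluded] == 0))
})

test_that("training refuses too-small pools and masks out dilated lesions", {
  v <- mk_feature_vols(8L)
  fs <- assemble_features(v$lsyn, v$lflair, v$atlas, v$wm, v$gm)
  expect_error(train_fusion(fs, n_samples = 50000L), "too few")

  # with an exclusion mask covering one route entirely, training must fail
  v2 <- mk_feature_vols(16L)
  fs2 <- assemble_features(v2$lsyn, v2$lflair, v2$atlas, v2$wm, v2$gm)
  mask <- volume_grid(array(1, dim(v2$wm$data)))
  expect_error(
    train_fusion(list(fs2), lesion_exclusion_masks = list(mask),
                 n_samples = 2000L),
    "too few")
})
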