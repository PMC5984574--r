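test_that("kernel regression matches direct summation and its closed forms", {
  # constant response
  expect_equal(kernel_regress(c(1, 2, 3), rep(7, 3), 0.5, seq(0, 4, 0.5)),
               rep(7, 9))
  # symmetric weights at the midpoint
  expect_equal(kernel_regress(c(500, 1000), c(800, 1200), 200, 750), 1000)

  set.seed(13)
  for (rep_i in 1:200) {
    n <- sample(1:30, 1)
    t <- runif(n, 0, 1500)
    f <- runif(n, 0, 2000)
    h <- runif(1, 5, 300)
    k <- runif(1, 0, 1600)
    expect_equal(kernel_regress(t, f, h, k), nw_oracle(t, f, h, k),
                 tolerance = 1e-9)
  }

  expect_error(kernel_regress(numeric(0), numeric(0), 1, 1), "non-empty")
  expect_error(kernel_regress(1, 1, -1, 1), "positive")
})

test_that("far extrapolation returns the nearest predictor's response", {
  # single tight cluster, evaluation far outside the kernel's reach
  t <- rnorm(50, 1000, 5)
  f <- rnorm(50, 900, 5)
  out <- kernel_regress(t, f, 10, c(0, 1500))
  expect_equal(out[1], f[which.min(abs(t - 0))])
  expect_equal(out[2], f[which.min(abs(t - 1500))])
})

test_that("voxel curves are flat in uniform tissue and structured across
           tissue boundaries", {
  banks <- small_banks()
  bank <- banks$bank
  cohort <- small_healthy_cohort()
  s <- cohort[[1]]
  shp <- dim(s$t1$data)

  # a voxel whose whole 5^3 patch is pure WM: single intensity cluster, so
  # the curve extrapolates one FLAIR intensity across the whole T1 range
  wm_all <- s$wm_prob$data == 1
  cand <- which(wm_all, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 2 & cand[, 1] < shp[1] - 1 &
                 cand[, 2] > 2 & cand[, 2] < shp[2] - 1 &
                 cand[, 3] > 2 & cand[, 3] < shp[3] - 1, , drop = FALSE]
  pure <- apply(cand, 1, function(ix)
    all(wm_all[(ix[1] - 2):(ix[1] + 2), (ix[2] - 2):(ix[2] + 2),
               (ix[3] - 2):(ix[3] + 2)]))
  expect_true(any(pure))
  ix <- cand[which(pure)[1], ]
  vox <- ix[1] + (ix[2] - 1) * shp[1] + (ix[3] - 1) * shp[1] * shp[2]
  curve <- bank$curves[, bank$index_map[vox]]
  f_wm <- s$flair$data[wm_all]
  expect_lt(max(curve) - min(curve), 2 * sd(f_wm))
  expect_lt(sd(curve), sd(f_wm))
  expect_equal(length(curve), bank$m)

  # a WM/GM interface voxel maps GM-like T1 to brighter FLAIR than WM-like
  # T1 (GM is darker on T1 but brighter on FLAIR)
  gm_idx <- which(s$gm_prob$data == 1, arr.ind = TRUE)
  ctr <- (shp + 1) / 2
  rad <- sqrt(rowSums(sweep(gm_idx, 2, ctr)^2))
  b_idx <- gm_idx[which.min(rad), ]
  vox_b <- b_idx[1] + (b_idx[2] - 1) * shp[1] + (b_idx[3] - 1) * shp[1] * shp[2]
  curve_b <- bank$curves[, bank$index_map[vox_b]]
  fp <- attr(s, "fixed_points")$t1
  i_gm <- ceiling(bank$m * 0.60 * fp$scale / bank$t_max)   # GM-like T1 index
  i_wm <- ceiling(bank$m * 0.80 * fp$scale / bank$t_max)   # WM-like T1 index
  expect_gt(curve_b[i_gm], curve_b[i_wm] + 25)

  # the full three-tissue pattern (CSF dark, GM peak, WM intermediate on
  # FLAIR) yields an interior maximum at GM-like T1 intensity
  set.seed(8)
  t <- c(rnorm(300, 357, 30), rnorm(300, 857, 30), rnorm(300, 1143, 30))
  f <- c(rnorm(300, 276, 30), rnorm(300, 1100, 30), rnorm(300, 900, 30))
  grid <- 1500 * (1:100) / 100
  m3 <- kernel_regress(t, f, 50, grid)
  imax <- which.max(m3)
  expect_gt(grid[imax], 600)
  expect_lt(grid[imax], 1100)
  expect_gt(max(m3), m3[100] + 50)
  expect_gt(max(m3), m3[1] + 50)
})

test_that("the transfer function is an identity for perfect synthesis and a
           median across subjects", {
  set.seed(4)
  vols <- lapply(1:3, function(i)
    volume_grid(array(runif(1000, 500, 1500), c(10, 10, 10))))
  tf_id <- estimate_transfer(vols, vols)
  mid <- tf_id$knots >= 600 & tf_id$knots <= 1400
  expect_equal(tf_id$median[mid], tf_id$knots[mid], tolerance = 5)

  # subjects whose true maps have slopes 0.9 / 1.0 / 1.1: median slope 1
  base <- volume_grid(array(runif(1000, 500, 1500), c(10, 10, 10)))
  flairs <- lapply(c(0.9, 1, 1.1), function(sl)
    volume_grid(base$data * sl, base$spacing))
  tf <- estimate_transfer(list(base, base, base), flairs)
  expect_equal(apply_transfer(1000, tf), 1000, tolerance = 5)

  expect_warning(estimate_transfer(vols[1], vols[1]), "fewer than 2")
})

test_that("the transfer correction restores compressed contrast", {
  cohort <- small_healthy_cohort()
  flairs <- lapply(cohort, `[[`, "flair")
  # contrast-compressed copies: intensities pulled halfway to the mean
  compressed <- lapply(flairs, function(f) {
    m <- mean(f$data[f$data > 0])
    out <- f$data
    out[out > 0] <- m + 0.5 * (out[out > 0] - m)
    volume_grid(out, f$spacing)
  })
  tf <- estimate_transfer(compressed, flairs)
  f1 <- flairs[[1]]$data[flairs[[1]]$data > 0]
  c1 <- compressed[[1]]$data[compressed[[1]]$data > 0]
  restored <- apply_transfer(c1, tf)
  spread <- function(x) diff(quantile(x, c(0.05, 0.95), names = FALSE))
  expect_lt(abs(spread(restored) / spread(f1) - 1), 0.05)
})

test_that("synthesis indexes curves by capped T1 and caps periventricular WM", {
  banks <- small_banks()
  bank <- banks$bank
  # index arithmetic: i = ceiling(m t / t_max), clamped
  expect_equal(ceiling(bank$m * 750 / bank$t_max), 50)
  s <- small_healthy_cohort()[[1]]
  synth <- synthesise(s$t1, bank)
  # above-cap T1 maps to the last curve entry: force one voxel above t_max
  t1_hot <- s$t1
  vox <- which(bank$index_map > 0)[1]
  t1_hot$data[vox] <- 1800
  synth_hot <- synthesise(t1_hot, bank, apply_transfer = FALSE,
                          apply_cap = FALSE)
  expect_equal(synth_hot$data[vox],
               bank$curves[bank$m, bank$index_map[vox]])
  # capping: no WM voxel in the periventricular shell exceeds its cap
  shell <- bank$pv_shell$data > 0
  expect_true(all(synth$data[shell] <= bank$pv_cap$data[shell] + 1e-9))
  # background synthesises to zero
  expect_true(all(synth$data[bank$index_map == 0] == 0))
})

test_that("the synthesis residual is the plain signed difference", {
  s <- small_healthy_cohort()[[1]]
  expect_true(all(compute_lsyn(s$flair, s$flair)$data == 0))
  a <- volume_grid(array(1300, c(2, 2, 2)))
  b <- volume_grid(array(1000, c(2, 2, 2)))
  expect_true(all(compute_lsyn(a, b)$data == 300))

  # healthy subject: residuals are noise-scale
  banks <- small_banks()
  synth <- synthesise(s$t1, banks$bank)
  lsyn <- compute_lsyn(s$flair, synth)
  brain <- s$t1$data > 0
  # voxel-level noise = tissue texture (0.04) plus scanner noise (0.02)
  noise_units <- sqrt(0.04^2 + 0.02^2) * attr(s, "fixed_points")$flair$scale
  expect_lt(mean(abs(lsyn$data[brain])), 2 * noise_units)
})

test_that("pseudo-healthy synthesis flattens T1-visible lesions", {
  banks <- small_banks()
  s <- normalise_bundle(small_lesioned_subject())
  synth <- synthesise(s$t1, banks$bank)
  lsyn <- compute_lsyn(s$flair, synth)
  les <- s$lesion_truth$data > 0
  wm_healthy <- s$wm_prob$data == 1
  expect_gt(mean(lsyn$data[les]),
            quantile(lsyn$data[wm_healthy], 0.95, names = FALSE))
  # synthetic intensity inside the lesion stays near healthy WM
  f_wm <- s$flair$data[wm_healthy]
  expect_lt(abs(mean(synth$data[les]) - mean(f_wm)), 2 * sd(f_wm))
})
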