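test_that("EM recovers well-separated mixture parameters", {
  ok <- 0L
  for (seed in 1:3) {
    set.seed(seed)
    x <- c(rnorm(2500, 900, 30), rnorm(2500, 1100, 40))
    fit <- em_fit_two_component(x)
    mus <- sort(fit$mu)
    if (abs(mus[1] - 900) <= 10 && abs(mus[2] - 1100) <= 10) ok <- ok + 1L
  }
  expect_gte(ok, 2L)
})

test_that("EM respects its contracts: two components, weights, monotone
           log-likelihood, degenerate input", {
  set.seed(5)
  x <- c(rnorm(500, 900, 30), rnorm(500, 1100, 40))
  fit <- em_fit_two_component(x)
  expect_length(fit$w, 2L)
  expect_length(fit$mu, 2L)
  expect_equal(sum(fit$w), 1, tolerance = 1e-9)
  expect_true(all(fit$sigma >= 1))
  # observed-data log-likelihood never decreases across iterations
  expect_true(all(diff(fit$loglik) >= -1e-6))
  expect_true(fit$converged)

  same <- em_fit_two_component(rep(42, 100))
  expect_equal(same$mu, c(42, 42))
  expect_equal(same$sigma, c(1, 1))
  expect_true(same$converged)

  # zeros are background padding, never data
  via_zeros <- em_fit_two_component(c(rep(0, 50), x))
  expect_equal(sort(via_zeros$mu), sort(fit$mu))

  small <- em_fit_two_component(c(5, 5, 6))
  expect_true(small$fallback)
  expect_equal(small$mu[1], small$mu[2])

  expect_error(em_fit_two_component(rep(0, 10)), "nonzero")
})

test_that("the voxel bank separates boundary voxels and not interior ones", {
  # two-plateau training volumes: left half dark, right half bright
  set.seed(9)
  shp <- c(14L, 8L, 8L)
  vols <- lapply(1:4, function(i) {
    a <- array(0, shp)
    a[1:7, , ] <- rnorm(7 * 64, 900, 20)
    a[8:14, , ] <- rnorm(7 * 64, 1100, 20)
    volume_grid(a)
  })
  bank <- fit_gmm_bank(vols, b = 5L)
  pick <- function(x, y, z) {
    v <- x + (y - 1) * shp[1] + (z - 1) * shp[1] * shp[2]
    bank$params[, bank$index_map[v]]
  }
  boundary <- pick(7L, 4L, 4L)    # patch straddles the plateaus
  interior <- pick(3L, 4L, 4L)    # patch sees one plateau only
  expect_gt(abs(boundary[3] - boundary[4]), 3 * max(boundary[5], boundary[6]))
  # interior components overlap heavily ("very similar"), far closer than
  # the boundary pair; on unimodal data the likelihood ridge is flat, so a
  # small residual split is expected
  expect_lt(abs(interior[3] - interior[4]),
            2 * max(interior[5], interior[6]))
  expect_lt(abs(interior[3] - interior[4]),
            0.2 * abs(boundary[3] - boundary[4]))
  # bimodal voxels converge quickly; diagnostics cover every fitted voxel
  bvox <- 7L + 3L * 14L + 3L * 14L * 8L
  expect_true(bank$converged[bank$index_map[bvox]])
  expect_length(bank$iterations, ncol(bank$params))
})

test_that("the abnormality map is zero below 1000 and matches the density
           oracle above", {
  set.seed(2)
  vols <- lapply(1:3, function(i)
    volume_grid(array(rnorm(512, 1100, 50), c(8, 8, 8))))
  bank <- fit_gmm_bank(vols, b = 3L)

  # sweep: a test volume covering intensities on both sides of the gate
  f <- volume_grid(array(seq(500, 1500, length.out = 512), c(8, 8, 8)))
  lf <- compute_lflair(f, bank)
  expect_true(all(lf$data[f$data < 1000] == 0))
  expect_true(all(lf$data >= 0))

  # density variant against a hand-coded two-Gaussian density
  lfd <- compute_lflair(f, bank, variant = "density")
  v <- which(f$data >= 1000)[5]
  p <- bank$params[, bank$index_map[v]]
  d_oracle <- p[1] * exp(-(f$data[v] - p[3])^2 / (2 * p[5]^2)) /
    (p[5] * sqrt(2 * pi)) +
    p[2] * exp(-(f$data[v] - p[4])^2 / (2 * p[6]^2)) / (p[6] * sqrt(2 * pi))
  expect_equal(lfd$data[v], d_oracle, tolerance = 1e-9)
  expect_true(all(lfd$data[f$data < 1000] == 0))

  # monotone in abnormality on the hyperintense side: the map at the
  # dominant mean is no larger than at mean + 5 sd
  mu_dom <- max(p[3], p[4])
  sd_dom <- p[c(5, 6)][which.max(p[c(3, 4)])]
  probe <- function(val) {
    fv <- f
    fv$data[v] <- val
    compute_lflair(fv, bank)$data[v]
  }
  expect_lte(probe(max(mu_dom, 1000)), probe(mu_dom + 5 * sd_dom))
})

test_that("identical components give the closed-form Gaussian neg-log density", {
  # build a bank whose fitted voxel is effectively a single Gaussian
  set.seed(3)
  vols <- lapply(1:3, function(i)
    volume_grid(array(rnorm(27 * 4, 1100, 50), c(6, 6, 3))))
  bank <- fit_gmm_bank(vols, b = 5L)
  v <- which(bank$index_map > 0)[1]
  p <- bank$params[, bank$index_map[v]]
  f <- 1100
  d <- p[1] * dnorm(f, p[3], p[5]) + p[2] * dnorm(f, p[4], p[6])
  fvol <- volume_grid(array(1100, dim(vols[[1]]$data)))
  lfd <- compute_lflair(fvol, bank, variant = "density")
  expect_equal(lfd$data[v], d, tolerance = 1e-9)
})
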