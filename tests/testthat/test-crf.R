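rand_unary <- function(shape, spacing = c(1, 1, 1), seed = 1L,
                       intensity_sd = 5) {
  set.seed(seed)
  n <- prod(shape)
  s <- volume_grid(array(stats::rexp(n, 1 / 50), shape), spacing)
  list(unary = build_unary(s, tau = 50),
       intensity = volume_grid(array(rnorm(n, 100, intensity_sd), shape),
                               spacing))
}

test_that("the unary bridge has its closed forms", {
  s <- volume_grid(array(c(0, 50, 1e6), c(3, 1, 1)))
  u <- build_unary(s, tau = 50, eps = 1e-6)
  p <- exp(-u$u1$data)
  expect_equal(p[1], 1e-6)
  expect_equal(p[2], 1 - exp(-1), tolerance = 1e-9)
  expect_equal(p[3], 1 - 1e-6)
  expect_equal(as.numeric(exp(-u$u0$data) + p), rep(1, 3), tolerance = 1e-9)
  expect_error(build_unary(s, tau = 0), "positive")
})

test_that("zero pairwise weight reduces mean field to the unary argmax", {
  rw <- rand_unary(c(5, 5, 5), seed = 3L)
  params <- crf_params(w1 = 0, w2 = 0)
  out <- meanfield_crf(rw$unary, rw$intensity, params, active_eps = 0)
  argmax <- (rw$unary$u1$data < rw$unary$u0$data) * 1
  expect_identical(out$data, argmax)
})

test_that("mean-field marginals are valid probabilities", {
  rw <- rand_unary(c(6, 6, 6), seed = 5L)
  out <- meanfield_crf(rw$unary, rw$intensity, crf_params(), active_eps = 0)
  q1 <- attr(out, "q1")
  expect_true(all(q1 >= 0 & q1 <= 1))
  expect_true(all(out$data %in% c(0, 1)))
})

test_that("exhaustive MAP on tiny grids: definitional properties", {
  # single voxel with a lesion-favouring unary
  s <- volume_grid(array(1000, c(1, 1, 1)))
  u <- build_unary(s, tau = 10)
  out <- exact_map_small(u, volume_grid(array(100, c(1, 1, 1))))
  expect_equal(as.numeric(out$data), 1)

  # two equal-intensity voxels, strong appearance coupling, opposing
  # unaries: both take the label of the stronger unary
  u2 <- list(u0 = volume_grid(array(c(3, 0.2), c(2, 1, 1))),
             u1 = volume_grid(array(c(0.2, 3), c(2, 1, 1))))
  iv <- volume_grid(array(c(100, 100), c(2, 1, 1)))
  # short-range appearance kernel so the single pair carries real weight
  strong <- crf_params(w1 = 0, w2 = 40, sigma_beta = 0.6, sigma_gamma = 10)
  out2 <- exact_map_small(u2, iv, strong)
  expect_equal(out2$data[1], out2$data[2])

  # returned labelling minimises the energy over all alternatives
  rw <- rand_unary(c(2, 2, 2), seed = 11L)
  best <- exact_map_small(rw$unary, rw$intensity, crf_params())
  e_best <- attr(best, "energy")
  for (code in 0:255) {
    lab <- as.integer(intToBits(code))[1:8]
    e <- lesionsynth:::crf_energy(rw$unary, rw$intensity, lab, crf_params())
    expect_gte(e + 1e-9, e_best)
  }

  expect_error(exact_map_small(rand_unary(c(4, 4, 4))$unary,
                               volume_grid(array(0, c(4, 4, 4)))),
               "too large")
})

test_that("mean field tracks the exact MAP on small grids", {
  agree <- numeric(0)
  for (seed in 1:10) {
    rw <- rand_unary(c(2, 2, 3), seed = seed)
    params <- crf_params()
    mf <- meanfield_crf(rw$unary, rw$intensity, params, active_eps = 0)
    ex <- lesionsynth:::crf_enum_map(rw$unary, rw$intensity, params)
    agree <- c(agree, mean(mf$data == ex$data))
  }
  expect_gte(mean(agree), 0.95)
})

test_that("an isolated positive voxel amid equal intensities is suppressed", {
  shp <- c(11, 11, 11)
  s <- volume_grid(array(0, shp))
  s$data[6, 6, 6] <- 200              # lesion-favouring unary (p ~ 0.98)
  u <- build_unary(s, tau = 50)
  iv <- volume_grid(array(100, shp))  # perfectly homogeneous intensity
  out <- meanfield_crf(u, iv, crf_params(w2 = 8), active_eps = 0)
  expect_equal(sum(out$data), 0)
  # with no pairwise terms the voxel survives, confirming the kernels did it
  out0 <- meanfield_crf(u, iv, crf_params(w1 = 0, w2 = 0), active_eps = 0)
  expect_equal(sum(out0$data), 1)
  expect_equal(which(out0$data == 1), which(s$data > 0))
})

test_that("the default parameters carry the tuned CRF values", {
  p <- crf_params()
  expect_equal(p$w2, 8)
  expect_equal(p$sigma_gamma, 2.5)
})
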