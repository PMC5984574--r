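test_that("overlap metrics match the set oracle on random masks", {
  set.seed(31)
  for (i in 1:40) {
    shp <- sample(3:10, 3, replace = TRUE)
    a <- random_mask(shp, runif(1, 0.1, 0.5))
    b <- random_mask(shp, runif(1, 0.1, 0.5))
    if (sum(a$data) == 0 || sum(b$data) == 0) next
    got <- overlap_metrics(seg_pair(a, b))
    want <- overlap_oracle(a$data, b$data)
    expect_equal(got$dsc, want$dsc, tolerance = 1e-12)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_true(all(unlist(got) >= 0 & unlist(got) <= 1))
  }
  # conventions
  e <- volume_grid(array(0, c(3, 3, 3)))
  f <- volume_grid(array(1, c(3, 3, 3)))
  expect_equal(overlap_metrics(seg_pair(e, e)),
               list(dsc = 1, precision = 1, recall = 1))
  expect_equal(overlap_metrics(seg_pair(e, f))$dsc, 0)
  expect_equal(overlap_metrics(seg_pair(f, f)),
               list(dsc = 1, precision = 1, recall = 1))
})

test_that("surface metrics match the all-pairs oracle, with hd >= assd", {
  # two single-voxel masks three 1 mm voxels apart
  a <- volume_grid(array(0, c(8, 4, 4))); a$data[2, 2, 2] <- 1
  b <- volume_grid(array(0, c(8, 4, 4))); b$data[5, 2, 2] <- 1
  sm <- surface_metrics(seg_pair(a, b))
  expect_equal(sm$assd, 3)
  expect_equal(sm$hd, 3)

  ident <- surface_metrics(seg_pair(a, a))
  expect_equal(ident$assd, 0)
  expect_equal(ident$hd, 0)

  e <- volume_grid(array(0, c(8, 4, 4)))
  expect_true(is.na(surface_metrics(seg_pair(a, e))$assd))

  set.seed(17)
  for (i in 1:15) {
    shp <- sample(4:8, 3, replace = TRUE)
    sp <- runif(3, 0.5, 2)
    p <- random_mask(shp, 0.3, sp)
    t <- random_mask(shp, 0.3, sp)
    if (sum(p$data) == 0 || sum(t$data) == 0) next
    got <- surface_metrics(seg_pair(p, t))
    want <- surface_oracle(seg_pair(p, t))
    expect_equal(got$assd, want$assd, tolerance = 1e-9)
    expect_equal(got$hd, want$hd, tolerance = 1e-9)
    expect_gte(got$hd, got$assd)
  }
})

test_that("ICC(A,1) matches the ANOVA decomposition and penalises bias", {
  set.seed(23)
  t <- rnorm(6, 10, 3)
  a <- t + rnorm(6, 0, 0.5)
  got <- icc_a1(a, t)

  # oracle: mean squares from aov on the long-format two-rater table
  df <- data.frame(y = c(a, t),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  want <- (msr - mse) / (msr + mse + 2 / 6 * (msc - mse))
  expect_equal(got, want, tolerance = 1e-9)

  expect_equal(icc_a1(t, t), 1)
  expect_lt(icc_a1(t + 5, t), 1)      # absolute agreement penalises shift
  expect_error(icc_a1(t, t[1:3]), "length")
  expect_error(icc_a1(1:2, 1:2), "3 subjects")
})

test_that("volume-binned DSC assigns components and subjects to the printed
           bins", {
  # one 5-voxel lesion (0.005 ml): very small bin
  t <- volume_grid(array(0, c(12, 12, 12)))
  t$data[4:8, 6, 6] <- 1
  p <- t
  out <- volume_binned_dsc(list(seg_pair(p, t)), "lesion")
  expect_equal(out$n[out$bin == "<0.01 ml"], 1L)
  expect_equal(out$mean_dsc[out$bin == "<0.01 ml"], 1)
  expect_true(all(is.na(out$mean_dsc[out$n == 0])))

  # subject with 12 ml total reference volume lands in the 10-15 ml bin
  big <- volume_grid(array(0, c(30, 30, 30)))
  big$data[seq_len(12000)] <- 1
  outs <- volume_binned_dsc(list(seg_pair(big, big)), "subject")
  expect_equal(outs$n[outs$bin == "10-15 ml"], 1L)
  expect_equal(outs$mean_dsc[outs$bin == "10-15 ml"], 1)

  # bounding-box DSC: an imperfect prediction inside the box
  p2 <- volume_grid(array(0, c(12, 12, 12)))
  p2$data[4:6, 6, 6] <- 1   # 3 of 5 voxels hit
  out2 <- volume_binned_dsc(list(seg_pair(p2, t)), "lesion")
  expect_equal(out2$mean_dsc[out2$bin == "<0.01 ml"], 2 * 3 / (3 + 5))

  # components are 26-connected
  t26 <- volume_grid(array(0, c(6, 6, 6)))
  t26$data[2, 2, 2] <- 1; t26$data[3, 3, 3] <- 1
  expect_equal(max(lesion_components(t26)), 1L)
  expect_equal(max(lesion_components(t26, connectivity = 6L)), 2L)
})

test_that("agreement statistics match closed-form least squares", {
  set.seed(41)
  icv <- runif(10, 1300, 1600)
  t <- runif(10, 2, 30)
  a <- t * 1.05 + rnorm(10, 0, 0.6)
  got <- agreement_stats(a, t, icv)

  x <- t / icv; y <- a / icv
  n <- 10
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  d <- (y - x) / (0.5 * (y + x))
  expect_equal(got$slope, slope, tolerance = 1e-9)
  expect_equal(got$intercept, intercept, tolerance = 1e-9)
  expect_equal(got$sse, sum((y - slope * x - intercept)^2), tolerance = 1e-9)
  expect_equal(got$r2, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(got$rpc, 1.96 * sd(d), tolerance = 1e-9)
  expect_equal(got$cv, 100 * sd(d) / mean(0.5 * (x + y)), tolerance = 1e-9)
  expect_equal(got$mean_diff, mean(d), tolerance = 1e-12)
  expect_true(got$p_value >= 0 && got$p_value <= 1)

  # exact linear relation a = 1.1 t: slope 1.1, SSE 0
  ex <- agreement_stats(1.1 * t, t, icv)
  expect_equal(ex$slope, 1.1, tolerance = 1e-9)
  expect_equal(ex$sse, 0, tolerance = 1e-12)

  # identity: all the degenerate closed forms
  idn <- agreement_stats(t, t, icv)
  expect_equal(idn$slope, 1, tolerance = 1e-9)
  expect_equal(idn$intercept, 0, tolerance = 1e-12)
  expect_equal(idn$r2, 1)
  expect_equal(idn$rpc, 0)
  expect_equal(idn$mean_diff, 0)

  expect_error(agreement_stats(rep(1, 5), rep(2, 5), rep(1000, 5)),
               "zero-variance")
})

test_that("rank correlation matches rank-then-Pearson with ties", {
  set.seed(51)
  icv <- rep(1500, 8)
  v <- c(1, 2, 2, 3, 5, 5, 5, 9)
  fz <- c(0L, 1L, 1L, 2L, 3L, 3L, 4L, 6L)
  got <- fazekas_correlation(v, icv, fz)
  want <- cor(rank(v / icv), rank(fz))
  expect_equal(got, want, tolerance = 1e-12)

  # strictly monotone: rho = 1
  expect_equal(fazekas_correlation(1:6, rep(1, 6), 0:5), 1)
  # zero variance: undefined, reported missing
  expect_true(is.na(fazekas_correlation(1:6, rep(1, 6), rep(3L, 6))))
  expect_error(fazekas_correlation(1:3, rep(1, 3), c(0L, 7L, 1L)), "\\[0, 6\\]")
})
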