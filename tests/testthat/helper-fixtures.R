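# Shared fixtures, built in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# a small lesion-capable phantom configuration (WM shell fits 2 mm lesions)
small_params <- function(seed = 11L, n_lesions = 2L, ...) {
  phantom_params(shape = c(28L, 28L, 28L),
                 lesion_radius_range = c(1.5, 2), n_lesions = n_lesions,
                 seed = seed, ...)
}

small_healthy_cohort <- function(n = 4L, seed = 7L) {
  memo(sprintf("healthy_%d_%d", n, seed), {
    cohort <- generate_cohort(n, small_params(seed = seed), healthy = TRUE)
    lapply(cohort, normalise_bundle)
  })
}

small_lesioned_subject <- function(seed = 29L) {
  memo(sprintf("lesioned_%d", seed),
       generate_subject(small_params(seed = seed)))
}

# synthesis + GMM banks trained on the small healthy cohort
small_banks <- function() {
  memo("banks", {
    cohort <- small_healthy_cohort()
    list(bank = fit_model_bank(cohort),
         gmm = fit_gmm_bank(lapply(cohort, `[[`, "flair")))
  })
}

# random binary mask of a given shape with roughly `fill` foreground
random_mask <- function(shape, fill = 0.2, spacing = c(1, 1, 1)) {
  volume_grid(array(as.numeric(runif(prod(shape)) < fill), shape), spacing)
}

# independent direct-summation Nadaraya-Watson oracle (scalar loop)
nw_oracle <- function(t, f, h, k) {
  w <- sapply(seq_along(t), function(i) exp(-0.5 * ((k - t[i]) / h)^2) /
                sqrt(2 * pi))
  den <- sum(w)
  if (den < 1e-300) return(f[which.min(abs(t - k))])
  sum(w * f) / den
}
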