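test_that("known six-point signals transform as expected", {
  # exact tone at bin 1
  a <- 0.7
  x <- a * cos(2 * pi * (0:5) / 6)
  amps <- dft_amplitudes(x)
  expect_equal(unname(amps), c(a, 0, 0), tolerance = 1e-12)
  # all zeros
  expect_equal(unname(dft_amplitudes(rep(0, 6))), c(0, 0, 0))
  # impulse: brute-force oracle gives (1/3, 1/3, 1/6)
  expect_equal(unname(dft_amplitudes(c(1, 0, 0, 0, 0, 0))),
               c(1 / 3, 1 / 3, 1 / 6), tolerance = 1e-12)
  expect_error(dft_amplitudes(rep(1, 5)), "even")
  expect_error(dft_amplitudes(rep(1, 2)), "even")
})

test_that("amplitudes agree with the brute-force DFT sum on random input", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(c(6, 8, 12), 1)
    x <- rnorm(n)
    expect_equal(unname(dft_amplitudes(x)), dft_oracle(x),
                 tolerance = 1e-10)
  }
})

test_that("Parseval's identity holds for the one-sided amplitudes", {
  set.seed(43)
  for (i in 1:50) {
    x <- rnorm(6)
    amps <- dft_amplitudes(x)
    n <- length(x)
    mods2 <- c(sum(x)^2,                       # k = 0
               (amps[1:2] * n / 2)^2 * 2,      # k and its conjugate
               (amps[3] * n)^2)                # Nyquist
    expect_equal(sum(mods2) / n, sum(x^2), tolerance = 1e-10)
  }
})

test_that("effect sizes match hand-computed cases", {
  es <- effect_sizes(c(1, 2), c(0, 3))
  expect_equal(es$cliffs_delta, 0)    # 2 wins, 2 losses over 4 pairs
  expect_equal(es$cohens_d, 0)

  es2 <- effect_sizes(c(2, 3), c(0, 1))
  expect_equal(es2$cliffs_delta, 1)   # complete separation
  expect_equal(es2$cohens_d, 2 / sqrt(0.5), tolerance = 1e-12)

  same <- effect_sizes(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$cohens_d, 0)
  expect_equal(same$cliffs_delta, 0)
  expect_error(effect_sizes(c(1, 1), c(1, 1)), "pooled")
  expect_error(effect_sizes(numeric(0), 1), "non-empty")
})

test_that("a noiseless 1/year cohort separates fully from its null", {
  p <- cohort_params(n_participants = 20, baseline_log_sd = 0.3,
                     decay_sd = 0.2, assay_cv = 0, seasonal_amplitude = 0,
                     fluctuation_cv = 0.2 / sqrt(2),
                     fluctuation_spectrum = single_frequency(1),
                     rng_seed = 17)
  fits <- fit_cohort_decline(generate_cohort(p))
  s <- cohort_spectrum(fits, n_boot = 200, n_shuffle = 200, seed = 2)
  expect_gt(s$mean_amplitude[1], s$null_ci_high[1])
  # the refitted decline leaks some tone power into the other bins, but
  # the 1/year bin stays dominant and the others stay within their null
  expect_gt(s$mean_amplitude[1], 2 * max(s$mean_amplitude[2:3]))
  expect_true(all(s$mean_amplitude[2:3] <= s$null_ci_high[2:3]))
  expect_equal(s$cliffs_delta, 1)
  expect_lt(s$p_nonparametric, 0.01)
})

test_that("the shuffled null is calibrated at the 1/year bin", {
  # exchangeable (white) corrected data: the permutation p-value must be
  # roughly uniform, so the 95% band captures the observed ~95% of the time
  set.seed(47)
  hits <- replicate(30, {
    co <- generate_cohort(cohort_params(n_participants = 25,
                                        seasonal_amplitude = 0,
                                        fluctuation_spectrum = "white"))
    s <- cohort_spectrum(fit_cohort_decline(co), n_boot = 40,
                         n_shuffle = 200)
    s$mean_amplitude[1] >= s$null_ci_low[1] &&
      s$mean_amplitude[1] <= s$null_ci_high[1]
  })
  expect_gte(mean(hits), 0.8)
})

test_that("the null preserves each series' total power", {
  co <- generate_cohort(cohort_params(n_participants = 10, rng_seed = 19))
  fits <- fit_cohort_decline(co)
  s <- cohort_spectrum(fits, n_boot = 50, n_shuffle = 300, seed = 5)
  # mean amplitude-weighted power of null repeats matches the observed
  # within a few percent (permutation moves power between bins only)
  obs_power <- sum(c(2, 2, 4) * s$mean_amplitude^2)   # up to bin weights
  null_power <- sum(c(2, 2, 4) * s$null_mean^2)
  expect_equal(null_power / obs_power, 1, tolerance = 0.15)
})

test_that("spectra are reproducible under a fixed seed and guard inputs", {
  co <- generate_cohort(cohort_params(n_participants = 8, rng_seed = 23))
  fits <- fit_cohort_decline(co)
  s1 <- cohort_spectrum(fits, n_boot = 60, n_shuffle = 60, seed = 9)
  s2 <- cohort_spectrum(fits, n_boot = 60, n_shuffle = 60, seed = 9)
  expect_identical(s1, s2)
  expect_error(cohort_spectrum(fits[1:3]), "at least 5")
  expect_error(cohort_spectrum(fits, n_shuffle = 10), "n_shuffle")
})

test_that("zero-variance series are excluded with a warning", {
  co <- generate_cohort(cohort_params(n_participants = 8, rng_seed = 29))
  fits <- fit_cohort_decline(co)
  flat <- make_exp_series()
  fits[["flat"]] <- fit_decline(flat)
  expect_warning(
    s <- cohort_spectrum(fits, n_boot = 40, n_shuffle = 40, seed = 1),
    "zero-variance")
  expect_equal(s$n_participants, 8)
})
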