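test_that("with no stress noise both variants rest at the unit fixed point", {
  for (variant in c("classic", "gland_mass")) {
    p <- hpa_params(model_variant = variant, input_sigma = 0,
                    t_total = 200, burn_in = 0, record_dt = 1)
    tr <- simulate_hpa(p)
    cols <- intersect(c("x1", "x2", "x3", "P", "A"), names(tr))
    for (cn in cols)
      expect_lt(max(abs(tr[[cn]] - 1)), 1e-8)
  }
})

test_that("trajectories stay positive and are reproducible under a seed", {
  p <- hpa_params(t_total = 3 * 365.25, seed = 71)
  tr1 <- simulate_hpa(p)
  tr2 <- simulate_hpa(p)
  expect_identical(tr1$x3, tr2$x3)
  for (cn in c("u", "x1", "x2", "x3", "P", "A"))
    expect_gt(min(tr1[[cn]]), 0)
})

test_that("the linearized slow subsystem matches the closed form", {
  b <- 1 / 17
  lin <- linearize_hpa(hpa_params(bP = b, bA = b))
  # eigenvalues (b/3) * (-3 +/- i sqrt(3)) / 2 from the 2x2 Jacobian
  expected <- (b / 3) * (-3 + 1i * sqrt(3)) / 2
  expect_equal(sort(Re(lin$eigenvalues)), rep(Re(expected), 2),
               tolerance = 1e-12)
  expect_equal(sort(abs(Im(lin$eigenvalues))), rep(Im(expected), 2),
               tolerance = 1e-12)
  expect_equal(lin$resonance_period_days, 4 * pi * sqrt(3) / b,
               tolerance = 1e-10)
  expect_equal(lin$damping_ratio, sqrt(3) / 2, tolerance = 1e-10)
  # period x frequency identity (period in days, frequency per year)
  expect_equal(lin$resonance_period_days *
                 lin$resonance_frequency_per_year / 365.25, 1,
               tolerance = 1e-10)
  expect_error(linearize_hpa(hpa_params(model_variant = "classic")),
               "classic")
})

test_that("rescaling both turnover rates rescales the resonance exactly", {
  l1 <- linearize_hpa(hpa_params(bP = 1 / 17, bA = 1 / 17))
  l2 <- linearize_hpa(hpa_params(bP = 3 / 17, bA = 3 / 17))
  expect_equal(l2$resonance_frequency_per_year,
               3 * l1$resonance_frequency_per_year, tolerance = 1e-10)
  # asymmetric turnover still yields a conjugate pair
  la <- linearize_hpa(hpa_params(bP = 1 / 10, bA = 1 / 60))
  expect_equal(la$eigenvalues[1], Conj(la$eigenvalues[2]), tolerance = 1e-12)
})

test_that("a step response oscillates at the linearized period", {
  p <- hpa_params(input_sigma = 0, input_mean = 1.2, t_total = 900,
                  burn_in = 0, record_dt = 1)
  tr <- simulate_hpa(p)
  # estimate the slow Jacobian by regressing d(log P, log A)/dt on the
  # log deviations from the new fixed point (P = A = 1.2)
  pq <- cbind(log(tr$P) - log(1.2), log(tr$A) - log(1.2))
  dpq <- diff(pq)
  J <- t(lm.fit(pq[-nrow(pq), ], dpq)$coefficients)
  period_sim <- 2 * pi / abs(Im(eigen(J, only.values = TRUE)$values[1]))
  period_lin <- linearize_hpa(p)$resonance_period_days
  expect_lt(abs(period_sim / period_lin - 1), 0.1)
})

test_that("fast hormone rates do not affect the slow dynamics", {
  p1 <- hpa_params(a1 = 8, a2 = 8, a3 = 8, t_total = 12 * 365.25, seed = 73)
  p2 <- hpa_params(a1 = 80, a2 = 80, a3 = 80, dt = 0.001,
                   t_total = 12 * 365.25, seed = 73)
  # same slow-subsystem resonance regardless of hormone turnover
  expect_equal(linearize_hpa(p1)$resonance_period_days,
               linearize_hpa(p2)$resonance_period_days)
  # and comparable slow fluctuation size of windowed cortisol
  cv_of <- function(p) {
    co <- virtual_hair(simulate_hpa(p), decay_alpha = 0, assay_cv = 0,
                       seed = 1)
    mean(tapply(co$cortisol_pg_per_mg, co$participant_id,
                function(x) sd(x) / mean(x)))
  }
  expect_equal(cv_of(p1), cv_of(p2), tolerance = 0.25)
})

test_that("virtual hair reshapes a trajectory into analyzable segments", {
  p <- hpa_params(input_sigma = 0, t_total = 3 * 365.25, burn_in = 0,
                  record_dt = 1)
  tr <- simulate_hpa(p)
  co <- virtual_hair(tr, decay_alpha = 0, assay_cv = 0)
  expect_equal(length(unique(co$participant_id)), 3)
  expect_lt(max(abs(co$cortisol_pg_per_mg - 1)), 1e-8)

  # with an imposed decline the correction recovers it
  co2 <- virtual_hair(tr, decay_alpha = 2.2, assay_cv = 0)
  fits <- fit_cohort_decline(co2)
  for (f in fits) expect_equal(f$alpha, 2.2, tolerance = 1e-6)

  expect_error(virtual_hair(tr[tr$time_days < 100, ]), "insufficient")
})

test_that("gland-mass cohorts show the 1/year excess and classic ones do not", {
  run_one <- function(variant, seed, assay_cv) {
    p <- hpa_params(model_variant = variant, t_total = 55 * 365.25,
                    seed = seed)
    co <- virtual_hair(simulate_hpa(p), assay_cv = assay_cv, seed = seed + 1)
    cohort_spectrum(fit_cohort_decline(co), n_boot = 100, n_shuffle = 300,
                    seed = seed)
  }
  # gland-mass without assay noise isolates the resonance: the 1/year bin
  # must clear the null band
  gland <- vapply(1:3, function(i) {
    s <- run_one("gland_mass", 80 + i, assay_cv = 0)
    s$mean_amplitude[1] > s$null_ci_high[1]
  }, logical(1))
  expect_gte(sum(gland), 2)

  # classic under realistic measurement noise is the null-like case
  classic <- run_one("classic", 90, assay_cv = 0.14)
  expect_lt(classic$mean_amplitude[1], classic$null_ci_high[1])
})

test_that("the sensitivity scan reports the year-scale excess across the grid", {
  grid <- data.frame(tP = c(17, 10), tA = c(17, 60))
  res <- sensitivity_scan(grid, n_participants = 30, n_boot = 60,
                          n_shuffle = 100,
                          base_params = hpa_params(t_total = 365.25),
                          seed = 5)
  expect_equal(nrow(res), 2)
  expect_true(all(res$amp_ratio_1_over_3 > 1))
  # symmetric point matches the closed form; asymmetric point matches a
  # direct numeric eigen-decomposition
  expect_equal(res$resonance_period_days[1], 4 * pi * sqrt(3) * 17,
               tolerance = 1e-8)
  J <- rbind(c(-1 / 10, -1 / 10), c(1 / 60, -2 / 60)) / 3
  expect_equal(res$resonance_period_days[2],
               2 * pi / abs(Im(eigen(J, only.values = TRUE)$values[1])),
               tolerance = 1e-8)
  expect_error(sensitivity_scan(data.frame()), "empty|tP")
})

test_that("parameter validation enforces stability and burn-in rules", {
  expect_error(hpa_params(dt = 0.05), "dt")
  expect_error(hpa_params(burn_in = 10), "burn_in")
  expect_error(hpa_params(bP = 0), "bP")
})
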