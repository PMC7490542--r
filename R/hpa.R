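#' Parameters of the HPA-axis simulators
#'
#' Dimensionless models of the hypothalamus-pituitary-adrenal cascade with
#' the steady state normalized to 1 for every variable at baseline stress
#' `u = 1`. The `classic` variant contains only the fast hormonal feedback
#' (cortisol inhibits CRH and ACTH secretion), so all its timescales are
#' the hour-scale hormone turnover times. The `gland_mass` variant adds the
#' slow feedback through the functional masses of the pituitary
#' corticotrophs (P) and adrenal cortex (A), whose week-scale turnover
#' produces a damped resonance with a period of about a year
#' (see [linearize_hpa()]).
#'
#' @param model_variant `"classic"` or `"gland_mass"`.
#' @param a1,a2,a3 turnover rates (1/day) of CRH, ACTH and cortisol;
#'   defaults of 8/day correspond to hour-scale half-lives.
#' @param bP,bA turnover rates (1/day) of corticotroph and adrenal-cortex
#'   functional mass; the default 1/17 per day (17-day turnover) puts the
#'   linearized resonance period at about 370 days.
#' @param input_sigma stationary sd of the stress input around its mean.
#' @param input_tau correlation time (days) of the stress input. The default
#'   (15 days, week-scale stressful episodes) is far below the year-scale
#'   resonance, so the input is effectively white for the slow subsystem;
#'   together with `input_sigma = 0.5` it puts the slow fluctuation CV of
#'   simulated cortisol near the ~22% seen in real hair data.
#' @param input_mean mean stress input (1 = baseline; a constant step is
#'   obtained with `input_sigma = 0` and `input_mean != 1`).
#' @param dt Euler-Maruyama step, days; must satisfy
#'   `dt < 0.1/max(a1,a2,a3)`.
#' @param t_total recorded span after burn-in, days.
#' @param burn_in discarded initial span, days; for `gland_mass` at least
#'   `5/min(bP,bA)` so the slow subsystem forgets its initial state.
#' @param record_dt spacing of recorded samples, days.
#' @param seed integer seed, or `NULL`.
#' @return an `hpa_params` object.
#' @export
hpa_params <- function(model_variant = c("gland_mass", "classic"),
                       a1 = 8, a2 = 8, a3 = 8,
                       bP = 1 / 17, bA = 1 / 17,
                       input_sigma = 0.5, input_tau = 15,
                       input_mean = 1,
                       dt = 0.01, t_total = 2 * 365.25,
                       burn_in = NULL, record_dt = 0.5,
                       seed = NULL) {
  model_variant <- match.arg(model_variant)
  for (nm in c("a1", "a2", "a3", "bP", "bA"))
    check_scalar(get(nm), nm, lower = 0, strict = TRUE)
  check_scalar(input_sigma, "input_sigma", lower = 0)
  check_scalar(input_tau, "input_tau", lower = 0, strict = TRUE)
  check_scalar(input_mean, "input_mean", lower = 0, strict = TRUE)
  check_scalar(dt, "dt", lower = 0, strict = TRUE)
  check_scalar(t_total, "t_total", lower = 0, strict = TRUE)
  if (dt >= 0.1 / max(a1, a2, a3))
    stop_param("dt", sprintf(
      "must be < 0.1/max(a1,a2,a3) = %.4g days for a stable explicit step",
      0.1 / max(a1, a2, a3)))
  min_burn <- if (model_variant == "gland_mass") 5 / min(bP, bA) else
    5 / min(a1, a2, a3)
  if (is.null(burn_in)) burn_in <- min_burn
  check_scalar(burn_in, "burn_in", lower = 0)
  # stochastic runs must forget the initial state; deterministic runs start
  # at the unit fixed point and the transient itself is of interest
  if (input_sigma > 0 && burn_in < min_burn)
    stop_param("burn_in", sprintf("must be >= %.4g days for this variant",
                                  min_burn))
  check_scalar(record_dt, "record_dt", lower = dt)
  structure(list(
    model_variant = model_variant,
    a1 = a1, a2 = a2, a3 = a3, bP = bP, bA = bA,
    input_sigma = input_sigma, input_tau = input_tau,
    input_mean = input_mean,
    dt = dt, t_total = t_total, burn_in = burn_in,
    record_dt = record_dt, seed = seed
  ), class = "hpa_params")
}

#' Simulate an HPA-axis trajectory
#'
#' Integrates the chosen model variant by Euler-Maruyama on the log of the
#' state (so all hormone levels and gland masses stay positive), driven by
#' an Ornstein-Uhlenbeck stress input clipped below at a small positive
#' floor. The burn-in span is discarded.
#'
#' @param params an [hpa_params()] object.
#' @param u_floor lower clip of the stress input.
#' @return an `hpa_trajectory` data.frame with columns `time_days`, `u`,
#'   `x1` (CRH), `x2` (ACTH), `x3` (cortisol) and, for the gland-mass
#'   variant, `P` and `A`.
#' @export
simulate_hpa <- function(params, u_floor = 0.01) {
  if (!inherits(params, "hpa_params"))
    stop("`params` must be created by hpa_params()", call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  rec_every <- max(1L, as.integer(round(params$record_dt / params$dt)))
  raw <- hpa_sim_cpp(
    gland_mass = params$model_variant == "gland_mass",
    a1 = params$a1, a2 = params$a2, a3 = params$a3,
    bP = params$bP, bA = params$bA,
    sigma = params$input_sigma, tau = params$input_tau,
    u_mean = params$input_mean, u_floor = u_floor,
    dt = params$dt, t_total = params$t_total, burn_in = params$burn_in,
    record_every = rec_every)
  traj <- as.data.frame(raw)
  structure(traj, params = params,
            class = c("hpa_trajectory", "data.frame"))
}

#' Linearized slow subsystem of the gland-mass model
#'
#' With hormone turnover (hours) much faster than gland turnover (weeks),
#' the hormones are at quasi-steady state given the gland masses, and the
#' slow dynamics of `(ln P, ln A)` around the fixed point reduce to a 2x2
#' linear system with Jacobian `(1/3) * [[-bP, -bP], [bA, -2*bA]]`. For
#' `bP = bA = b` the eigenvalues are `(b/3) * (-3 +/- i*sqrt(3))/2`, a
#' damped oscillation with period `2*pi/Im = 4*pi*sqrt(3)/b` (about 370
#' days for a 17-day turnover time): week-scale tissue turnover yields a
#' year-scale resonance because period = 2*pi/frequency.
#'
#' @param params an [hpa_params()] object with `model_variant = "gland_mass"`.
#' @return a `linear_analysis` list: complex `eigenvalues` (1/day),
#'   `resonance_frequency_per_year`, `resonance_period_days`
#'   (`2*pi/|Im lambda|`), `damping_ratio`.
#' @export
linearize_hpa <- function(params) {
  if (!inherits(params, "hpa_params"))
    stop("`params` must be created by hpa_params()", call. = FALSE)
  if (params$model_variant != "gland_mass")
    stop("the classic variant has no slow subsystem to linearize",
         call. = FALSE)
  J <- rbind(c(-params$bP, -params$bP),
             c(params$bA, -2 * params$bA)) / 3
  ev <- eigen(J, only.values = TRUE)$values
  im <- abs(Im(ev[1]))
  structure(list(
    jacobian = J,
    eigenvalues = ev,
    resonance_frequency_per_year = if (im > 0) im / (2 * pi) * DAYS_PER_YEAR
                                   else NA_real_,
    resonance_period_days = if (im > 0) 2 * pi / im else NA_real_,
    damping_ratio = -Re(ev[1]) / Mod(ev[1])
  ), class = "linear_analysis")
}

#' Cut a simulated cortisol trajectory into virtual hair segments
#'
#' Averages simulated cortisol over consecutive windows of
#' `segment_months`, then groups consecutive non-overlapping blocks of
#' `n_segments` windows into independent virtual participants — the
#' simulated analogue of cutting a hair sample into 2-cm segments. To mimic
#' real data the segments can be multiplied by an imposed exponential
#' decline along the hair and by lognormal assay noise (both on by
#' default), after which the cohort is analyzed by the identical
#' correction + spectrum pipeline as real hair.
#'
#' @param trajectory an `hpa_trajectory` from [simulate_hpa()].
#' @param n_segments segments per virtual participant.
#' @param segment_months months of growth per segment.
#' @param decay_alpha imposed decline coefficient (1/year; 0 disables).
#' @param assay_cv imposed multiplicative assay noise CV (0 disables).
#' @param start_date calendar date assigned to the start of the trajectory
#'   (collection dates are staggered accordingly).
#' @param seed integer seed for the imposed noise, or `NULL`.
#' @return a `hair_cohort` data.frame (see [generate_cohort()]).
#' @export
virtual_hair <- function(trajectory, n_segments = 6, segment_months = 2,
                         decay_alpha = 2.2, assay_cv = 0.14,
                         start_date = as.Date("2015-01-01"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seg_days <- segment_months * DAYS_PER_YEAR / MONTHS_PER_YEAR
  t <- trajectory$time_days
  x3 <- trajectory$x3
  # the last recorded sample sits one record step before the window edge
  dt_rec <- median(diff(t))
  n_windows <- floor((max(t) - min(t) + dt_rec) / seg_days)
  n_part <- floor(n_windows / n_segments)
  if (n_part < 1)
    stop(sprintf(
      "insufficient data: trajectory spans %.0f days, need at least %.0f",
      max(t) - min(t), n_segments * seg_days), call. = FALSE)
  window <- floor((t - min(t)) / seg_days)
  keep <- window < n_part * n_segments
  win_fac <- factor(window[keep], levels = 0:(n_part * n_segments - 1))
  win_mean <- tapply(x3[keep], win_fac, mean)

  t_years <- segment_midpoint_years(n_segments, segment_months, 1)
  sig <- sigma_from_cv(assay_cv)
  rows <- vector("list", n_part)
  for (i in seq_len(n_part)) {
    block <- win_mean[((i - 1) * n_segments + 1):(i * n_segments)]
    conc <- rev(block)                      # segment 1 = most recent window
    conc <- conc * exp(-decay_alpha * t_years)
    if (assay_cv > 0)
      conc <- conc * rlnorm(n_segments, -sig^2 / 2, sig)
    rows[[i]] <- data.frame(
      participant_id = sprintf("V%03d", i),
      collection_date = start_date + round(i * n_segments * seg_days),
      segment_index = seq_len(n_segments),
      cortisol_pg_per_mg = as.numeric(conc)
    )
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  structure(cohort,
            params = list(segment_length_cm = segment_months,
                          growth_rate_cm_per_month = 1),
            class = c("hair_cohort", "data.frame"))
}

#' Spectrum summaries over a grid of tissue turnover times
#'
#' For each pair of turnover times (days) of the pituitary corticotrophs
#' and adrenal cortex, simulates the gland-mass model, converts the
#' cortisol trajectory to virtual hair, runs the decline correction and
#' cohort spectrum, and records whether the 1/year amplitude exceeds the
#' shuffled-null 97.5% line together with the 1-vs-3 amplitude ratio and
#' the linearized resonance period.
#'
#' @param turnover_times data.frame (or matrix) with columns `tP`, `tA` in
#'   days.
#' @param n_participants virtual participants per grid point.
#' @param n_boot,n_shuffle resampling sizes passed to [cohort_spectrum()].
#' @param base_params an [hpa_params()] whose rates other than `bP`, `bA`
#'   are reused.
#' @param seed integer seed.
#' @return data.frame with one row per grid point: `tP`, `tA`,
#'   `amp_ratio_1_over_3`, `a1_above_null`, `p_nonparametric`,
#'   `resonance_period_days`.
#' @export
sensitivity_scan <- function(turnover_times, n_participants = 55,
                             n_boot = 200, n_shuffle = 200,
                             base_params = hpa_params(), seed = 1) {
  grid <- as.data.frame(turnover_times)
  if (nrow(grid) == 0) stop("turnover grid is empty", call. = FALSE)
  if (!all(c("tP", "tA") %in% names(grid)))
    stop("grid must have columns tP and tA", call. = FALSE)
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- base_params
    p$bP <- 1 / grid$tP[g]
    p$bA <- 1 / grid$tA[g]
    p$burn_in <- max(p$burn_in, 5 / min(p$bP, p$bA))
    p$t_total <- n_participants * DAYS_PER_YEAR
    p$seed <- seed + g
    cohort <- virtual_hair(simulate_hpa(p), seed = seed + g)
    fits <- fit_cohort_decline(cohort)
    spec <- cohort_spectrum(fits, n_boot = n_boot, n_shuffle = n_shuffle,
                            seed = seed + g)
    lin <- linearize_hpa(p)
    res[[g]] <- data.frame(
      tP = grid$tP[g], tA = grid$tA[g],
      amp_ratio_1_over_3 = spec$amp_ratio_1_over_3,
      a1_above_null = spec$mean_amplitude[1] > spec$null_ci_high[1],
      p_nonparametric = spec$p_nonparametric,
      resonance_period_days = lin$resonance_period_days
    )
  }
  do.call(rbind, res)
}
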