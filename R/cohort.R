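#' Parameters of a synthetic hair-cortisol cohort
#'
#' Bundles the knobs of the synthetic cohort generator. Defaults reproduce
#' the statistical structure of real longitudinal hair cortisol: six 2-cm
#' segments (about one year of growth at 1 cm/month), roughly 30-fold
#' between-person baseline spread, mean exponential decline of 2.2/year along
#' the hair, 14% multiplicative assay noise, a 15% seasonal component peaking
#' in late winter, and slow biological fluctuations with CV 22%.
#'
#' @param n_participants number of individuals.
#' @param n_segments segments per individual (>= 4 so the spectrum has at
#'   least two positive frequencies).
#' @param segment_length_cm length of each segment, cm.
#' @param growth_rate_cm_per_month hair growth rate; 1 cm/month is the
#'   standard conversion between hair position and time.
#' @param baseline_median median scalp-level baseline, pg/mg.
#' @param baseline_log_sd sd of the natural log of the between-person
#'   baseline. The default 0.68 gives a max/min ratio of order 30 across
#'   55 individuals.
#' @param decay_mean,decay_sd mean and sd (1/year) of the per-individual
#'   exponential decline coefficient; draws are truncated at zero.
#' @param assay_cv coefficient of variation of the multiplicative lognormal
#'   assay noise.
#' @param seasonal_amplitude fractional amplitude of the seasonal
#'   (12-month cosinor) modulation of cortisol.
#' @param seasonal_acrophase_month month-of-year in \[0, 12) at which the
#'   seasonal factor peaks (0 = Jan 1). Default 1.5 (mid-February,
#'   late winter).
#' @param fluctuation_cv coefficient of variation of the slow biological
#'   fluctuation process around the individual baseline.
#' @param fluctuation_spectrum frequency content of the fluctuation process:
#'   `"white"` (independent between segments), `"one_over_f"` (spectral
#'   synthesis with amplitude proportional to 1/f on a monthly grid,
#'   window-averaged per segment), or `single_frequency(f)` for a pure tone
#'   at `f` cycles/year with random phase per individual.
#' @param collection_start,collection_end calendar interval (`Date` or
#'   coercible) over which collection dates are drawn uniformly.
#' @param rng_seed integer seed making [generate_cohort()] reproducible, or
#'   `NULL` to use the current RNG state.
#' @return an object of class `cohort_params`.
#' @seealso [generate_cohort()], [single_frequency()]
#' @export
cohort_params <- function(n_participants = 55,
                          n_segments = 6,
                          segment_length_cm = 2,
                          growth_rate_cm_per_month = 1,
                          baseline_median = 10,
                          baseline_log_sd = 0.68,
                          decay_mean = 2.2,
                          decay_sd = 0.5,
                          assay_cv = 0.14,
                          seasonal_amplitude = 0.15,
                          seasonal_acrophase_month = 1.5,
                          fluctuation_cv = 0.22,
                          fluctuation_spectrum = "one_over_f",
                          collection_start = as.Date("2017-01-01"),
                          collection_end = as.Date("2017-12-31"),
                          rng_seed = NULL) {
  check_scalar(n_participants, "n_participants", lower = 1)
  check_scalar(n_segments, "n_segments", lower = 4)
  if (n_segments %% 2 != 0)
    stop_param("n_segments", "must be even (paired DFT bins)")
  check_scalar(segment_length_cm, "segment_length_cm", lower = 0, strict = TRUE)
  check_scalar(growth_rate_cm_per_month, "growth_rate_cm_per_month",
               lower = 0, strict = TRUE)
  check_scalar(baseline_median, "baseline_median", lower = 0, strict = TRUE)
  check_scalar(baseline_log_sd, "baseline_log_sd", lower = 0)
  check_scalar(decay_mean, "decay_mean")
  check_scalar(decay_sd, "decay_sd", lower = 0)
  check_scalar(assay_cv, "assay_cv", lower = 0)
  check_scalar(seasonal_amplitude, "seasonal_amplitude", lower = 0)
  if (seasonal_amplitude >= 1)
    stop_param("seasonal_amplitude", "must be < 1 (factor must stay positive)")
  check_scalar(seasonal_acrophase_month, "seasonal_acrophase_month")
  check_scalar(fluctuation_cv, "fluctuation_cv", lower = 0)
  spec <- normalize_spectrum(fluctuation_spectrum)
  collection_start <- as.Date(collection_start)
  collection_end <- as.Date(collection_end)
  if (collection_end < collection_start)
    stop_param("collection_date_range", "end precedes start")
  structure(list(
    n_participants = as.integer(n_participants),
    n_segments = as.integer(n_segments),
    segment_length_cm = segment_length_cm,
    growth_rate_cm_per_month = growth_rate_cm_per_month,
    baseline_median = baseline_median,
    baseline_log_sd = baseline_log_sd,
    decay_mean = decay_mean,
    decay_sd = decay_sd,
    assay_cv = assay_cv,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_acrophase_month = seasonal_acrophase_month,
    fluctuation_cv = fluctuation_cv,
    fluctuation_spectrum = spec,
    collection_start = collection_start,
    collection_end = collection_end,
    rng_seed = rng_seed
  ), class = "cohort_params")
}

#' Single-frequency fluctuation spectrum
#'
#' Marks the fluctuation process as a pure tone at `frequency` cycles/year
#' with a uniformly random phase per individual. The tone's amplitude is
#' `sqrt(2) * fluctuation_cv`, so that the per-series CV equals
#' `fluctuation_cv` (the CV of `1 + a*cos` is `a/sqrt(2)`).
#'
#' @param frequency cycles per year.
#' @export
single_frequency <- function(frequency = 1) {
  check_scalar(frequency, "frequency", lower = 0, strict = TRUE)
  structure(list(type = "single_frequency", frequency = frequency),
            class = "fluctuation_spectrum")
}

normalize_spectrum <- function(spec) {
  if (inherits(spec, "fluctuation_spectrum")) return(spec)
  if (is.character(spec) && length(spec) == 1L &&
      spec %in% c("white", "one_over_f"))
    return(structure(list(type = spec), class = "fluctuation_spectrum"))
  stop_param("fluctuation_spectrum",
             'must be "white", "one_over_f" or single_frequency(f)')
}

#' Generate a synthetic hair-cortisol cohort
#'
#' Each individual's segment concentrations are built multiplicatively as
#' `C_i(t) = B_i * exp(-alpha_i * t) * S(month(t)) * F_i(t) * eps`,
#' where `t` is the segment midpoint time before collection (years), `B_i`
#' is a lognormal between-person baseline, `alpha_i` a normal decline
#' coefficient truncated at zero, `S` the seasonal cosinor factor
#' `1 + A*cos(2*pi*(month - acrophase)/12)`, `F_i` the slow biological
#' fluctuation process scaled to the requested CV, and `eps` multiplicative
#' lognormal assay noise.
#'
#' @param params a [cohort_params()] object.
#' @return a `hair_cohort`: a data.frame with columns `participant_id`,
#'   `collection_date`, `segment_index` (1 = scalp-proximal) and
#'   `cortisol_pg_per_mg`, carrying `params` as an attribute.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_participants = 10, rng_seed = 1))
#' head(cohort)
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params"))
    stop("`params` must be created by cohort_params()", call. = FALSE)
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  p <- params
  n <- p$n_participants
  ns <- p$n_segments
  t_years <- segment_midpoint_years(ns, p$segment_length_cm,
                                    p$growth_rate_cm_per_month)

  baseline <- p$baseline_median * exp(rnorm(n, 0, p$baseline_log_sd))
  alpha <- rnorm(n, p$decay_mean, p$decay_sd)
  if (p$decay_sd > 0) {
    # truncate at zero; with realistic parameters resampling is rare
    while (any(bad <- alpha <= 0))
      alpha[bad] <- rnorm(sum(bad), p$decay_mean, p$decay_sd)
  }
  span <- as.numeric(p$collection_end - p$collection_start)
  dates <- p$collection_start + round(runif(n, 0, span))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    midpoint_dates <- dates[i] - t_years * DAYS_PER_YEAR
    seasonal <- 1 + p$seasonal_amplitude *
      cos(2 * pi * (frac_month(midpoint_dates) - p$seasonal_acrophase_month) /
            MONTHS_PER_YEAR)
    fluct <- draw_fluctuation(p, t_years)
    eps <- rlnorm(ns, meanlog = -sigma_from_cv(p$assay_cv)^2 / 2,
                  sdlog = sigma_from_cv(p$assay_cv))
    conc <- baseline[i] * exp(-alpha[i] * t_years) * seasonal * fluct * eps
    rows[[i]] <- data.frame(
      participant_id = sprintf("P%03d", i),
      collection_date = dates[i],
      segment_index = seq_len(ns),
      cortisol_pg_per_mg = conc
    )
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  structure(cohort, params = p,
            class = c("hair_cohort", "data.frame"))
}

# one draw of the fluctuation factor F(t) at the segment midpoints
draw_fluctuation <- function(p, t_years) {
  cv <- p$fluctuation_cv
  ns <- length(t_years)
  if (cv == 0) return(rep(1, ns))
  spec <- p$fluctuation_spectrum
  switch(spec$type,
    white = exp(rnorm(ns, 0, sigma_from_cv(cv))),
    single_frequency = {
      a <- sqrt(2) * cv
      phase <- runif(1, 0, 2 * pi)
      1 + a * cos(2 * pi * spec$frequency * t_years + phase)
    },
    one_over_f = exp(one_over_f_series(p, t_years, sigma_from_cv(cv)))
  )
}

# 1/f log-fluctuations: spectral synthesis on a monthly grid over a window
# four times the hair span (so frequencies below 1/year contribute), then
# averaged over each segment's months. The deterministic scale factor sets
# the expected within-series sample variance of the averaged, sampled
# process to sigma_target^2: power below 1/span mostly moves the series
# mean, which does not contribute to the per-series CV.
one_over_f_series <- function(p, t_years, sigma_target) {
  months_per_seg <- p$segment_length_cm / p$growth_rate_cm_per_month
  span_months <- ceiling(length(t_years) * months_per_seg)
  M <- 4 * span_months                   # synthesis period, months
  k <- seq_len(floor(M / 2))
  f_k <- k / M                           # cycles per month
  c_k <- 1 / f_k                         # amplitude ~ 1/f
  L <- max(1L, round(months_per_seg))    # months averaged per segment
  # a length-L boxcar scales a tone's amplitude by the Dirichlet kernel
  w_k <- abs(sin(pi * f_k * L) / (L * sin(pi * f_k)))
  w_k[f_k == 0] <- 1
  # expected sample variance across the n sampled segments for a random
  # phase tone: (c w)^2/2 * (1 - |D|^2) * n/(n-1), D the mean phasor
  n_seg <- length(t_years)
  D2 <- vapply(f_k, function(f) {
    Mod(mean(exp(2i * pi * f * L * (seq_len(n_seg) - 0.5))))^2
  }, numeric(1))
  v <- sum((c_k * w_k)^2 / 2 * (1 - D2)) * n_seg / (n_seg - 1)
  c_k <- c_k * sigma_target / sqrt(v)
  phases <- runif(length(k), 0, 2 * pi)
  # month index of each sample inside the synthesis window (most recent last)
  grid <- seq_len(span_months)
  g <- colSums(c_k * cos(outer(2 * pi * f_k, grid) + phases))
  # average consecutive L-month windows; segment 1 is the most recent
  seg_of <- rep(seq_len(length(t_years)), each = L)[seq_along(grid)]
  as.numeric(tapply(rev(g), seg_of, mean))[seq_along(t_years)]
}

#' Extract per-participant hair series from a cohort table
#'
#' @param cohort a `hair_cohort` data.frame (or any data.frame with the same
#'   columns).
#' @param segment_length_cm,growth_rate_cm_per_month geometry used to convert
#'   segment index into time before collection; taken from the cohort's
#'   generator parameters when present.
#' @return a named list of `hair_series` objects, each with
#'   `participant_id`, `collection_date`, `concentrations` (segment 1 first)
#'   and `segment_midpoint_times` (years before collection).
#' @export
hair_series_list <- function(cohort, segment_length_cm = NULL,
                             growth_rate_cm_per_month = NULL) {
  p <- attr(cohort, "params")
  if (is.null(segment_length_cm))
    segment_length_cm <- if (!is.null(p)) p$segment_length_cm else 2
  if (is.null(growth_rate_cm_per_month))
    growth_rate_cm_per_month <-
      if (!is.null(p)) p$growth_rate_cm_per_month else 1
  split_rows <- split(seq_len(nrow(cohort)), cohort$participant_id)
  lapply(split_rows, function(idx) {
    block <- cohort[idx, ]
    block <- block[order(block$segment_index), ]
    conc <- block$cortisol_pg_per_mg
    structure(list(
      participant_id = block$participant_id[1],
      collection_date = as.Date(block$collection_date[1]),
      concentrations = conc,
      segment_midpoint_times = segment_midpoint_years(
        length(conc), segment_length_cm, growth_rate_cm_per_month)
    ), class = "hair_series")
  })
}

#' Write / read a cohort as CSV
#'
#' The on-disk schema is `participant_id, collection_date (ISO 8601),
#' segment_index, cortisol_pg_per_mg`; [read_cohort()] validates it
#' (positive concentrations, no duplicated segments, parseable dates) and
#' warns about participants whose segment count differs from the modal one.
#'
#' @param cohort a `hair_cohort` (or compatible data.frame).
#' @param path file path.
#' @return `read_cohort` returns a `hair_cohort` data.frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(
    participant_id = cohort$participant_id,
    collection_date = format(as.Date(cohort$collection_date), "%Y-%m-%d"),
    segment_index = cohort$segment_index,
    cortisol_pg_per_mg = cohort$cortisol_pg_per_mg
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "collection_date", "segment_index",
            "cortisol_pg_per_mg")
  if (!all(need %in% names(raw)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dates <- as.Date(raw$collection_date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stop(sprintf("row %d: unparseable collection_date '%s'",
                 bad, raw$collection_date[bad]), call. = FALSE)
  }
  conc <- suppressWarnings(as.numeric(raw$cortisol_pg_per_mg))
  if (anyNA(conc) || any(conc <= 0)) {
    bad <- which(is.na(conc) | conc <= 0)[1]
    stop(sprintf("row %d: cortisol_pg_per_mg must be a positive number (got '%s')",
                 bad, raw$cortisol_pg_per_mg[bad]), call. = FALSE)
  }
  key <- paste(raw$participant_id, raw$segment_index)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop(sprintf("row %d: duplicate (participant, segment) pair '%s'",
                 bad, key[bad]), call. = FALSE)
  }
  counts <- table(raw$participant_id)
  modal <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
  short <- names(counts)[counts != modal]
  if (length(short) > 0)
    warning("participants with a segment count differing from the modal ",
            modal, ": ", paste(short, collapse = ", "), call. = FALSE)
  cohort <- data.frame(
    participant_id = raw$participant_id,
    collection_date = dates,
    segment_index = as.integer(raw$segment_index),
    cortisol_pg_per_mg = conc
  )
  structure(cohort, class = c("hair_cohort", "data.frame"))
}
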