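#' Fit the exponential decline of cortisol along one hair sample
#'
#' Ordinary least squares of log-concentration on segment midpoint time
#' (years before collection): `ln C_j = ln B - alpha * t_j + r_j`. The
#' intercept exponentiates to the baseline (the fitted scalp-level value at
#' collection time) and minus the slope is the decline coefficient `alpha`
#' (1/year). The log-residuals `r_j` are the decline-corrected signal used
#' by all downstream analyses; `exp(r_j)` is the normalized series.
#'
#' @param series a `hair_series` (see [hair_series_list()]), or a list with
#'   `concentrations` and `segment_midpoint_times`.
#' @return a `decline_fit` with `participant_id`, `baseline`, `alpha`,
#'   `log_residuals`, `normalized`, `fit_r2`, and the input series (kept so
#'   the shuffled null can re-run the identical correction).
#' @export
fit_decline <- function(series) {
  conc <- series$concentrations
  t <- series$segment_midpoint_times
  if (length(conc) < 3)
    stop("insufficient data: need at least 3 segments", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (length(t) != length(conc) || any(diff(t) <= 0))
    stop("segment times must be strictly increasing and match concentrations",
         call. = FALSE)
  y <- log(conc)
  fit <- ols_log_fit(y, t)
  structure(list(
    participant_id = series$participant_id,
    collection_date = series$collection_date,
    baseline = exp(fit$intercept),
    alpha = -fit$slope,
    log_residuals = fit$residuals,
    normalized = exp(fit$residuals),
    fit_r2 = fit$r2,
    concentrations = conc,
    segment_midpoint_times = t,
    method = "exponential"
  ), class = "decline_fit")
}

# shared OLS core: the same projection is used by fit_decline and by the
# matrix fast path of the shuffled null (cohort_spectrum)
ols_log_fit <- function(y, t) {
  tc <- t - mean(t)
  slope <- sum(tc * y) / sum(tc^2)
  intercept <- mean(y) - slope * mean(t)
  res <- y - (intercept + slope * t)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  list(intercept = intercept, slope = slope, residuals = res, r2 = r2)
}

# residual-maker matrix annihilating {1, t}; R = M %*% logC gives the
# decline-corrected log series for every column of logC at once
residual_projector <- function(t) {
  X <- cbind(1, t)
  diag(length(t)) - X %*% solve(crossprod(X), t(X))
}

#' Fit the decline for every participant of a cohort
#'
#' @param cohort a `hair_cohort` data.frame (see [generate_cohort()],
#'   [read_cohort()]).
#' @inheritParams hair_series_list
#' @return list of `decline_fit` objects.
#' @export
fit_cohort_decline <- function(cohort, segment_length_cm = NULL,
                               growth_rate_cm_per_month = NULL) {
  lapply(hair_series_list(cohort, segment_length_cm,
                          growth_rate_cm_per_month), fit_decline)
}

#' Cohort-level summary of decline fits
#'
#' @param fits list of `decline_fit` objects.
#' @return list with `mean_alpha`, `sem_alpha` (sample sd / sqrt(n)),
#'   `baseline_fold_range` (max/min fitted baseline) and `n`.
#' @export
cohort_decline_summary <- function(fits) {
  if (length(fits) < 2)
    stop("insufficient data: need at least 2 fits", call. = FALSE)
  alphas <- vapply(fits, `[[`, numeric(1), "alpha")
  baselines <- vapply(fits, `[[`, numeric(1), "baseline")
  list(
    mean_alpha = mean(alphas),
    sem_alpha = sd(alphas) / sqrt(length(alphas)),
    baseline_fold_range = max(baselines) / min(baselines),
    n = length(fits)
  )
}

#' Fluctuation CV with assay-noise subtraction
#'
#' Each participant's fluctuation size is the CV (sd/mean) of their
#' normalized (decline-corrected, linear-scale) series; the cohort mean CV
#' is then corrected for assay noise in quadrature,
#' `cv_corrected = sqrt(cv_raw^2 - assay_cv^2)`, since independent
#' multiplicative noise adds variance on top of biological fluctuations.
#'
#' @param fits list of `decline_fit` objects (or anything with a
#'   `normalized` field).
#' @param assay_cv assay coefficient of variation (fraction).
#' @param scale compute the per-participant CV on the `"linear"` normalized
#'   values (default) or as the sd of the `"log"` residuals.
#' @return a `fluctuation_stats` list: `per_participant_cv`, `mean_cv_raw`,
#'   `assay_cv`, `mean_cv_noise_corrected`.
#' @export
fluctuation_cv <- function(fits, assay_cv = 0.14,
                           scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  check_scalar(assay_cv, "assay_cv", lower = 0)
  cvs <- vapply(fits, function(f) {
    if (scale == "linear") sd(f$normalized) / mean(f$normalized)
    else sd(f$log_residuals)
  }, numeric(1))
  raw <- mean(cvs)
  if (assay_cv >= raw)
    stop(sprintf(
      "degenerate noise subtraction: assay_cv (%.3f) >= mean raw CV (%.3f)",
      assay_cv, raw), call. = FALSE)
  structure(list(
    per_participant_cv = cvs,
    mean_cv_raw = raw,
    assay_cv = assay_cv,
    mean_cv_noise_corrected = sqrt(raw^2 - assay_cv^2)
  ), class = "fluctuation_stats")
}

#' Non-parametric decline correction
#'
#' Model-free alternative to the per-individual exponential fit: the
#' across-cohort median log profile at each segment position is subtracted
#' from every individual's log series, and each individual's residuals are
#' then centered to zero mean. Requires all participants to share the same
#' segment count.
#'
#' @inheritParams fit_cohort_decline
#' @return list of `decline_fit`-like objects (method `"nonparametric"`,
#'   no `baseline`/`alpha`).
#' @export
nonparametric_correct <- function(cohort, segment_length_cm = NULL,
                                  growth_rate_cm_per_month = NULL) {
  series <- hair_series_list(cohort, segment_length_cm,
                             growth_rate_cm_per_month)
  ns <- vapply(series, function(s) length(s$concentrations), integer(1))
  if (length(unique(ns)) != 1)
    stop("all participants must share the same segment count; found counts ",
         paste(sort(unique(ns)), collapse = ", "), call. = FALSE)
  logC <- vapply(series, function(s) log(s$concentrations), numeric(ns[1]))
  R <- nonparametric_residuals(logC)
  out <- lapply(seq_along(series), function(i) {
    s <- series[[i]]
    structure(list(
      participant_id = s$participant_id,
      collection_date = s$collection_date,
      baseline = NA_real_,
      alpha = NA_real_,
      log_residuals = R[, i],
      normalized = exp(R[, i]),
      fit_r2 = NA_real_,
      concentrations = s$concentrations,
      segment_midpoint_times = s$segment_midpoint_times,
      method = "nonparametric"
    ), class = "decline_fit")
  })
  names(out) <- names(series)
  out
}

# cohort-median profile removal + per-individual centering, matrix form
nonparametric_residuals <- function(logC) {
  R <- logC - apply(logC, 1, median)
  sweep(R, 2, colMeans(R))
}
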