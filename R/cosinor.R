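#' Pooled 12-month cosinor of decline-corrected cortisol
#'
#' Estimates the cohort-level seasonal component of cortisol by regressing
#' log-residuals on `cos(2*pi*m/12)` and `sin(2*pi*m/12)`, where `m` is the
#' fractional calendar month-of-year of each hair segment's midpoint
#' (collection date minus the segment's time offset at 1 cm/month). The fit
#' is pooled across participants: a six-point individual series cannot
#' separate personal seasonality from a 1/year fluctuation, but collection
#' dates spread over the calendar let the cohort identify a common seasonal
#' rhythm. Because residuals are on a log scale, the cosinor amplitude is
#' (to first order) the fractional amplitude of the multiplicative seasonal
#' factor.
#'
#' When called on a list of decline fits, the cosine/sine regressors are
#' passed through each participant's own decline-correction projection
#' before the pooled regression. The per-individual detrend removes part of
#' any seasonal signal from the residuals; projecting the regressors the
#' same way (the Frisch-Waugh-Lovell construction) makes the amplitude
#' estimate equal to that of a joint fit of individual trends plus a shared
#' seasonal term, and therefore unbiased by the correction.
#'
#' @param month fractional month-of-year in \[0, 12) of each point (see
#'   [frac_month()]), or a list of `decline_fit` objects.
#' @param log_residual decline-corrected log values, same length as `month`
#'   (omit when `month` is a list of fits).
#' @return a `cosinor_fit`: `mesor`, `amplitude`, `amplitude_se` (delta
#'   method), `acrophase_month` in \[0, 12), `residual_cv` (CV of
#'   exp(residuals)), `n_points`, plus the coefficients.
#' @export
fit_cosinor <- function(month, log_residual = NULL) {
  if (is.list(month) && inherits(month[[1]], "decline_fit"))
    return(fit_cosinor_projected(month))
  if (length(month) != length(log_residual))
    stop("month and log_residual must have equal length", call. = FALSE)
  theta <- 2 * pi * month / MONTHS_PER_YEAR
  cosinor_ols(cbind(1, cos(theta), sin(theta)), log_residual, month)
}

fit_cosinor_projected <- function(fits) {
  blocks <- lapply(fits, function(f) {
    m <- frac_month(as.Date(f$collection_date) -
                      f$segment_midpoint_times * DAYS_PER_YEAR)
    theta <- 2 * pi * m / MONTHS_PER_YEAR
    P <- fit_projector(f)
    list(month = m, X = cbind(1, P %*% cos(theta), P %*% sin(theta)),
         y = f$log_residuals)
  })
  X <- do.call(rbind, lapply(blocks, `[[`, "X"))
  y <- unlist(lapply(blocks, `[[`, "y"), use.names = FALSE)
  month <- unlist(lapply(blocks, `[[`, "month"), use.names = FALSE)
  cosinor_ols(X, y, month)
}

# projection each fit applied to its data (and hence to the regressors)
fit_projector <- function(f) {
  n <- length(f$log_residuals)
  if (identical(f$method, "nonparametric"))
    diag(n) - matrix(1 / n, n, n)
  else
    residual_projector(f$segment_midpoint_times)
}

cosinor_ols <- function(X, y, month) {
  ok <- is.finite(y) & apply(is.finite(X), 1, all)
  X <- X[ok, , drop = FALSE]; y <- y[ok]; month <- month[ok]
  if (length(unique(round(month, 6))) < 3)
    stop("need at least 3 distinct calendar times", call. = FALSE)
  rng <- diff(range(month))
  if (rng < 4 && (MONTHS_PER_YEAR - rng) > 8)
    stop("calendar times must span more than 1/3 of a year", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("cosinor design is rank-deficient (all samples at the same month)",
         call. = FALSE)
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  amplitude <- sqrt(beta[2]^2 + beta[3]^2)
  acrophase <- (atan2(beta[3], beta[2]) / (2 * pi) * MONTHS_PER_YEAR) %%
    MONTHS_PER_YEAR
  sigma2 <- sum(res^2) / (length(res) - 3)
  XtXinv <- chol2inv(qr.R(qrX))
  g <- if (amplitude > 0) c(0, beta[2], beta[3]) / amplitude else c(0, 1, 0)
  amp_se <- sqrt(sigma2 * drop(t(g) %*% XtXinv %*% g))
  structure(list(
    mesor = unname(beta[1]),
    amplitude = unname(amplitude),
    amplitude_se = unname(amp_se),
    acrophase_month = unname(acrophase),
    residual_cv = sd(exp(res)) / mean(exp(res)),
    n_points = length(res),
    coef = c(mesor = unname(beta[1]), beta_cos = unname(beta[2]),
             beta_sin = unname(beta[3]))
  ), class = "cosinor_fit")
}

#' Remove the fitted seasonal component from a cohort
#'
#' Subtracts the cosinor's seasonal term from every participant's
#' log-residuals and recomputes the fluctuation statistics with assay-noise
#' subtraction. The subtracted term is the seasonal regressor passed
#' through the participant's own decline-correction projection, so the
#' deseasonalized residuals remain exactly what the joint fit (individual
#' trends + shared seasonality) would leave. Because the fitted term is
#' orthogonal to the remaining residuals, the cohort CV drops by
#' approximately `sqrt(cv^2 - A^2/2)` where `A` is the fitted amplitude.
#'
#' @param fits list of `decline_fit` objects (the cohort the cosinor was
#'   fitted on).
#' @param cosinor a `cosinor_fit` from [fit_cosinor()].
#' @param assay_cv assay CV used for the noise-corrected fluctuation CV.
#' @return list with `fits` (deseasonalized copies) and `stats`
#'   (a `fluctuation_stats` object).
#' @export
deseasonalize <- function(fits, cosinor, assay_cv = 0.14) {
  if (!inherits(cosinor, "cosinor_fit"))
    stop("`cosinor` must come from fit_cosinor()", call. = FALSE)
  n_expected <- sum(vapply(fits, function(f) length(f$log_residuals),
                           integer(1)))
  if (cosinor$n_points != n_expected)
    stop("cosinor was fitted on a different cohort (point count mismatch)",
         call. = FALSE)
  b <- cosinor$coef
  out <- lapply(fits, function(f) {
    m <- frac_month(as.Date(f$collection_date) -
                      f$segment_midpoint_times * DAYS_PER_YEAR)
    theta <- 2 * pi * m / MONTHS_PER_YEAR
    P <- fit_projector(f)
    seasonal <- drop(P %*% (b["beta_cos"] * cos(theta) +
                              b["beta_sin"] * sin(theta)))
    f$log_residuals <- f$log_residuals - seasonal
    f$normalized <- exp(f$log_residuals)
    f
  })
  list(fits = out, stats = fluctuation_cv(out, assay_cv = assay_cv))
}
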