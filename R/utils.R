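# internal helpers shared across modules

MONTHS_PER_YEAR <- 12
DAYS_PER_YEAR <- 365.25

#' Fractional month-of-year of a calendar date
#'
#' Maps dates to a continuous month coordinate in \[0, 12), anchored so that
#' 2000-01-01 maps to 0 and the cycle length is one mean year (365.25 days).
#' Used as the phase coordinate for the seasonal cosinor.
#'
#' @param date a `Date` vector (or numeric days since 1970-01-01).
#' @return numeric vector in \[0, 12).
#' @keywords internal
frac_month <- function(date) {
  d <- as.numeric(date) - as.numeric(as.Date("2000-01-01"))
  MONTHS_PER_YEAR * ((d %% DAYS_PER_YEAR) / DAYS_PER_YEAR)
}

# segment midpoint times in years before collection, segment 1 = scalp side
segment_midpoint_years <- function(n_segments, segment_length_cm = 2,
                                   growth_rate_cm_per_month = 1) {
  months <- segment_length_cm * (seq_len(n_segments) - 0.5) /
    growth_rate_cm_per_month
  months / MONTHS_PER_YEAR
}

# lognormal sigma giving a multiplicative factor a prescribed CV
sigma_from_cv <- function(cv) sqrt(log(1 + cv^2))

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(field, "must be a finite numeric scalar")
  if (strict && x <= lower)
    stop_param(field, sprintf("must be > %g", lower))
  if (!strict && x < lower)
    stop_param(field, sprintf("must be >= %g", lower))
  invisible(x)
}
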