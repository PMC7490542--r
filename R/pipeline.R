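#' Configuration of an end-to-end pipeline run
#'
#' Exactly one input source is taken: a cohort CSV on disk, synthetic
#' cohort parameters, or HPA-model parameters (whose simulated cortisol is
#' converted to virtual hair). The cohort then flows through decline
#' correction, fluctuation statistics, the Fourier spectrum with shuffled
#' null, and (optionally) cosinor seasonality correction followed by a
#' second spectrum on the deseasonalized residuals.
#'
#' @param cohort_csv path to a cohort CSV ([read_cohort()] schema), or `NULL`.
#' @param cohort_params a [cohort_params()] object, or `NULL`.
#' @param hpa a [hpa_params()] object, or `NULL`.
#' @param correction `"exponential"` or `"nonparametric"`.
#' @param assay_cv assay CV used in noise subtraction.
#' @param n_boot,n_shuffle resampling sizes for [cohort_spectrum()].
#' @param cosinor whether to fit and remove seasonality.
#' @param seed root seed; every stage draws from a seed derived from it.
#' @param out_dir directory for intermediate artifacts (cohort CSV, fits
#'   CSV, report JSON), or `NULL` to keep everything in memory.
#' @return a `run_config` object.
#' @export
run_config <- function(cohort_csv = NULL, cohort_params = NULL, hpa = NULL,
                       correction = c("exponential", "nonparametric"),
                       assay_cv = 0.14, n_boot = 1000, n_shuffle = 1000,
                       cosinor = TRUE, seed = 1, out_dir = NULL) {
  sources <- !vapply(list(cohort_csv, cohort_params, hpa), is.null,
                     logical(1))
  if (sum(sources) != 1)
    stop("exactly one input source (cohort_csv, cohort_params or hpa) ",
         "must be given", call. = FALSE)
  structure(list(
    cohort_csv = cohort_csv, cohort_params = cohort_params, hpa = hpa,
    correction = match.arg(correction), assay_cv = assay_cv,
    n_boot = n_boot, n_shuffle = n_shuffle, cosinor = cosinor,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Run the full hair-cortisol pipeline
#'
#' Stages, in order: load or generate the cohort; per-individual decline
#' correction; cohort decline summary and fluctuation CV with assay-noise
#' subtraction; Fourier spectrum with bootstrap SEM and shuffled null;
#' optionally a pooled cosinor fit, seasonal removal, and the spectrum of
#' the deseasonalized residuals. Identical config and seed give an
#' identical report.
#'
#' @param config a [run_config()] object.
#' @return a `run_report` list: `decline_summary`, `fluctuation`,
#'   `spectrum`, and when seasonality is on, `cosinor_fit`,
#'   `fluctuation_deseasonalized`, `spectrum_deseasonalized`; plus
#'   `provenance` (seed, stage record counts, package version).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop("`config` must come from run_config()", call. = FALSE)
  seed <- config$seed

  cohort <- if (!is.null(config$cohort_csv)) {
    read_cohort(config$cohort_csv)
  } else if (!is.null(config$cohort_params)) {
    p <- config$cohort_params
    p$rng_seed <- seed
    generate_cohort(p)
  } else {
    hp <- config$hpa
    hp$seed <- seed
    virtual_hair(simulate_hpa(hp), seed = seed + 1L)
  }

  fits <- if (config$correction == "exponential") fit_cohort_decline(cohort)
          else nonparametric_correct(cohort)
  summary <- if (config$correction == "exponential")
    cohort_decline_summary(fits) else NULL
  fluct <- fluctuation_cv(fits, assay_cv = config$assay_cv)
  spec <- cohort_spectrum(fits, n_boot = config$n_boot,
                          n_shuffle = config$n_shuffle, seed = seed + 2L)

  report <- list(
    decline_summary = summary,
    fluctuation = unclass(fluct[c("mean_cv_raw", "assay_cv",
                                  "mean_cv_noise_corrected")]),
    spectrum = unclass(spec)
  )

  if (isTRUE(config$cosinor)) {
    cos_fit <- fit_cosinor(fits)
    deseas <- deseasonalize(fits, cos_fit, assay_cv = config$assay_cv)
    spec2 <- cohort_spectrum(deseas$fits, n_boot = config$n_boot,
                             n_shuffle = config$n_shuffle, seed = seed + 3L)
    report$cosinor_fit <- cos_fit[c("mesor", "amplitude", "amplitude_se",
                                    "acrophase_month", "residual_cv",
                                    "n_points")]
    report$fluctuation_deseasonalized <-
      unclass(deseas$stats[c("mean_cv_raw", "assay_cv",
                             "mean_cv_noise_corrected")])
    report$spectrum_deseasonalized <- unclass(spec2)
  }

  report$provenance <- list(
    seed = seed,
    correction = config$correction,
    n_participants = length(fits),
    n_boot = config$n_boot,
    n_shuffle = config$n_shuffle,
    package_version = as.character(utils::packageVersion("hairspec"))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    write_fits_csv(fits, file.path(config$out_dir, "fits.csv"))
    write_report(report, file.path(config$out_dir, "report.json"))
  }
  structure(report, class = "run_report")
}

#' Write decline fits as CSV
#'
#' Columns: `participant_id`, `baseline`, `alpha`, `r2`, then
#' `residual_1..residual_n`.
#'
#' @param fits list of `decline_fit` objects.
#' @param path file path.
#' @export
write_fits_csv <- function(fits, path) {
  ns <- length(fits[[1]]$log_residuals)
  res <- t(vapply(fits, `[[`, numeric(ns), "log_residuals"))
  colnames(res) <- paste0("residual_", seq_len(ns))
  out <- data.frame(
    participant_id = vapply(fits, `[[`, character(1), "participant_id"),
    baseline = vapply(fits, `[[`, numeric(1), "baseline"),
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    r2 = vapply(fits, `[[`, numeric(1), "fit_r2"),
    res
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline report as JSON
#'
#' @param report a `run_report` (or any list).
#' @param path file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_recursive(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}
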