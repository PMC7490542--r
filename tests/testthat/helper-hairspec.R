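# shared fixtures and independent oracles

# a noiseless exponential series: C(t) = baseline * exp(-alpha * t)
make_exp_series <- function(baseline = 10, alpha = 2.2, n = 6,
                            collection_date = as.Date("2017-06-15")) {
  t <- (seq_len(n) - 0.5) / 6   # years; 2-cm segments at 1 cm/month
  list(participant_id = "T01",
       collection_date = collection_date,
       concentrations = baseline * exp(-alpha * t),
       segment_midpoint_times = t)
}

# brute-force DFT-sum oracle, independent of the fft-based implementation
dft_oracle <- function(x) {
  n <- length(x)
  ks <- seq_len(n / 2)
  vapply(ks, function(k) {
    Xk <- sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
    if (k < n / 2) 2 * Mod(Xk) / n else Mod(Xk) / n
  }, numeric(1))
}

# cohort parameters with every noise source silenced
silent_params <- function(...) {
  cohort_params(baseline_log_sd = 0, decay_sd = 0, assay_cv = 0,
                seasonal_amplitude = 0, fluctuation_cv = 0, ...)
}
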