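# Shared fixtures: small configurations keeping unit tests fast. The
# acceptance tests use the full default parameters instead.

# reduced frequency grid for unit tests of the wavelet machinery
quick_wp <- function(nf = 16, lo = 1, hi = 12, dt = 1 / 60) {
  wavelet_params(freqs = exp(seq(log(lo), log(hi), length.out = nf)), dt = dt)
}

# small session: n short trials per condition, no long trials
quick_counts <- function(n_short = 3L) {
  tc <- default_trial_counts()
  tc[, "short"] <- as.integer(n_short)
  tc[, "long"] <- 0L
  tc
}

# a clean deterministic trial: no stochastic components unless overridden
noiseless_config <- function(rate = 5, noise_sd = 0, ...) {
  sim_config(tapping_rate = rate, phase_jitter_sd = 0, rate_drift_sd = 0,
             tremor_sd = 0, baseline_drift_sd = 0, noise_sd = noise_sd,
             outlier_rate = 0, ...)
}

# tiny decoder settings for pipeline-level tests
quick_dp <- function(...) {
  decoder_params(n_components = 10L, window_len = 30L, window_step = 10L,
                 n_datasets = 2L, ...)
}
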