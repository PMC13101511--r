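# Shared fixtures: the study-condition truth (pyrene at 60 mg/L, triplicates
# over 15 days) and noise-free / noisy generators used across test files.

study_params <- function() kinetic_params(k_tot = 0.142, f = 0.4437,
                                          k2 = 0.150, S0 = 60)

noiseless_design <- function(...) {
  design_spec(noise_sigma_parent = 0, noise_sigma_intermediate = 0,
              lod_parent = 0, lod_intermediate = 0, ...)
}

noiseless_data <- function(params = study_params()) {
  simulate_timecourse(params, noiseless_design())
}

# Random valid parameter draws for property tests (rates spanning the
# plausible degradation range, f over (0,1), S0 over tens of mg/L).
random_params <- function(n, seed = 1, degenerate = FALSE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k_tot <- stats::runif(1, 0.02, 1)
    k2 <- if (degenerate) k_tot + stats::runif(1, -1, 1) * 1e-9
          else stats::runif(1, 0.01, 1)
    kinetic_params(k_tot = k_tot, f = stats::runif(1, 0.05, 0.95),
                   k2 = k2, S0 = stats::runif(1, 10, 300))
  })
}
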