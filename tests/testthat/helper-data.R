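# Shared fixture builders. All randomness is seeded per call.

# Growth-only study conditions: full 8-point panels on every unit
# (certain survival, metamorphosis far beyond the measurement window),
# default treatment-structured gamma/alpha, cup-mean noise sigma mm.
growth_config <- function(seed, sigma = 0.5) {
  sim_config(seed = seed, sigma_resid = sigma, block_sd = 0,
             survival_prob_by_cell = cell_values(1),
             meta_day_mean_by_cell = cell_values(500))
}

# Fast fitting control for tests.
quick_control <- function(seed = 1014L, n_restarts = 4L) {
  gompertz_control(n_restarts = n_restarts, seed = seed)
}

# Effect-free endpoint configuration with a block random intercept.
null_endpoint_config <- function(seed, block_sd = 0.2, p = 0.8) {
  sim_config(seed = seed, block_sd = block_sd,
             survival_prob_by_cell = cell_values(stats::qlogis(p),
                                                 trans = stats::plogis),
             meta_day_mean_by_cell = cell_values(50),
             meta_length_mean_by_cell = cell_values(17))
}
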