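# Shared fixtures for the suite. Everything is generated in code; the short
# integration spans used here are enough for the properties checked and keep
# the suite fast.

short_settings <- function(t_end = 200, h = NULL) {
  integration_settings(h = h, t_end = t_end)
}

# Pure-decay configuration: no synthesis, no recycling. x decays at rate
# k_rx + k_dx, z at k_dz, y relaxes under constant controls.
decay_params <- function() {
  suppressWarnings(model_params(k_x = 0, k_x0 = 0, k_rz = 0))
}

# The short-delay configuration used for most regime work.
short_delays <- function(tau_e = 3) delay_params(1, 2, 3, tau_e)

# Minimum and maximum varying-parameter sets of the recycling scans.
min_set <- function() suppressWarnings(
  model_params(h_x = 1, h_b = 5, k_x = 10, k_b = 100, K_a = 1))
max_set <- function(h_b = 15) model_params(h_x = 3, h_b = h_b, k_x = 40,
                                           k_b = 200, K_a = 3)

# Random smooth parameter draw for oracle comparisons: moderate rates and
# Hill coefficients so the reduced ODE is well inside the non-stiff regime.
random_smooth_params <- function() {
  suppressWarnings(model_params(
    k_a0 = runif(1, 0, 0.5), k_a = runif(1, 0.5, 2),
    K_a = runif(1, 0.5, 2), h_a = sample(1:2, 1),
    y0 = 1,
    k_b0 = runif(1, 0.2, 1), k_b = runif(1, 1, 10),
    K_b = runif(1, 2, 4), h_b = sample(1:4, 1),
    k_x0 = runif(1, 0, 0.5), k_x = runif(1, 1, 10),
    K_x = 1, h_x = sample(1:3, 1),
    k_dx = runif(1, 0.05, 0.3), k_rx = runif(1, 0.3, 1),
    k_dz = runif(1, 0.3, 1), k_rz = runif(1, 0, 1)
  ))
}
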