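# Reference parameter sets used across the suite.

reference_params <- function(...) model_params(...)

# lower and higher burst-size / clearance pairs (same alpha/q_v ratio family)
pair_low <- function(...) model_params(alpha = 580, q_v = 1.67e-1, ...)
pair_high <- function(...) model_params(alpha = 3500, q_v = 1.00, ...)

# stochastic-extinction experiment: 2D, high burst, halved clearance,
# infection spanning the whole tumour
extinction2d_params <- function(movement = "undirected", tau = 0.02, delta = 0.1) {
  model_params(alpha = 3500, q_v = 8.33e-2, R_v = 2.6, dimension = 2,
               movement = movement, tau = tau, delta = delta)
}

# a bare trajectory skeleton for the outcome estimators
fake_radial_traj <- function(t, int_U, int_I) {
  structure(list(kind = "pde", model = "U3", params = reference_params(),
                 x = seq(0, 1, 0.1), times = t,
                 u = NULL, i = NULL, v = NULL,
                 totals = data.frame(t = t, U = int_U, I = int_I),
                 radial = TRUE, nx = 11L, ny = 1L),
            class = "ov_trajectory")
}
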