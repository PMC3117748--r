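# Shared fixtures, built once per test run.

# Small adiabatic reference run: 20 mm cube at 1 mm, perfusion off, 20 s of
# heating in the default capsule mode, exact (direct) linear solves.
adiabatic_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        grid_extent = c(20, 20, 20), grid_spacing = 1,
        tissue = tissue_properties(perfusion = 0),
        duration_s = 20, linear_solver_tolerance = 1e-10
      )
      cache <<- simulate_fla(cfg, keep_history = TRUE)
    }
    cache
  }
})

# Constant-temperature history on a tiny grid.
constant_history <- function(temp_C, tau = 75, n_frames = 4) {
  g <- build_grid(c(2, 2, 2), 2)
  times <- seq(0, tau, length.out = n_frames)
  fields <- rep(list(rep(celsius_to_kelvin(temp_C), n_nodes(g))), n_frames)
  temperature_history(g, times, fields)
}

# Closed-form damage integral for a constant hold (the independent oracle).
omega_constant <- function(temp_C, tau, kin) {
  kin$frequency_factor * tau *
    exp(-kin$activation_energy / (kin$gas_constant * celsius_to_kelvin(temp_C)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
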