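test_that("uniform blood-temperature field with no source is a fixed point", {
  cfg <- sim_config(grid_extent = c(10, 10, 10), grid_spacing = 1,
                    source = fiber_source(power = 0, diffuser_length = 4,
                                          capsule_radius = 1))
  st <- assemble_source(cfg$grid, cfg$source)
  T0 <- scalar_field(cfg$grid, rep(cfg$tissue$blood_temperature, n_nodes(cfg$grid)))
  T1 <- step_temperature(T0, st, cfg)
  expect_lt(max(abs(T1$values - T0$values)), 1e-9)
  # and a whole zero-power run started at T_b stays at T_b
  cfg2 <- sim_config(grid_extent = c(10, 10, 10), grid_spacing = 1,
                     source = fiber_source(power = 0, diffuser_length = 4,
                                           capsule_radius = 1),
                     duration_s = 5)
  sim <- simulate_fla(cfg2, accumulate_damage = FALSE)
  expect_lt(max(abs(sim$final$values - cfg2$initial_temperature)), 1e-8)
})

test_that("perfusion-only cooling follows the closed-form exponential decay", {
  w_vol <- volumetric_perfusion_rate(tissue_properties())
  expect_equal(w_vol, 1.665e-3, tolerance = 1e-6)
  cfg <- sim_config(grid_extent = c(4, 4, 4), grid_spacing = 2,
                    tissue = tissue_properties(conductivity = 0),
                    source = fiber_source(power = 0, diffuser_length = 2,
                                          capsule_radius = 1),
                    initial_temperature_C = 45)
  sim <- simulate_fla(cfg, keep_history = TRUE, accumulate_damage = FALSE)
  T_exact_C <- 37 + 8 * exp(-w_vol * 75)
  got_C <- kelvin_to_celsius(sim$final$values[1])
  expect_equal(T_exact_C, 44.06, tolerance = 1e-3)       # printed value
  expect_lt(abs(got_C - T_exact_C) / 8, 1e-3)            # relative on the offset
  # the whole trajectory stays within tolerance, not just the endpoint
  for (i in c(31, 76, 151)) {
    t <- sim$history$times[i]
    expect_lt(abs(kelvin_to_celsius(sim$history$fields[[i]][1]) -
                    (37 + 8 * exp(-w_vol * t))) / 8, 1e-3)
  }
})

test_that("backward Euler without sources obeys the discrete maximum principle", {
  cfg <- sim_config(grid_extent = c(10, 10, 10), grid_spacing = 1,
                    tissue = tissue_properties(perfusion = 0),
                    source = fiber_source(power = 0, diffuser_length = 4,
                                          capsule_radius = 1),
                    duration_s = 10, dt_s = 0.5)
  st <- assemble_source(cfg$grid, cfg$source)
  set.seed(7)
  vals <- celsius_to_kelvin(stats::runif(n_nodes(cfg$grid), 20, 90))
  Tf <- scalar_field(cfg$grid, vals)
  lo <- min(vals); hi <- max(vals)
  sys <- littsim:::assemble_bioheat_system(cfg$grid, cfg$tissue, st, cfg$dt)
  for (k in 1:20) {
    Tf <- step_temperature(Tf, st, cfg, system = sys)
    expect_gte(min(Tf$values), lo - 1e-9)
    expect_lte(max(Tf$values), hi + 1e-9)
  }
})

test_that("adiabatic runs conserve energy", {
  sim <- adiabatic_sim()
  ts <- sim$config$tissue
  w <- node_weights(sim$config$grid)
  dH <- sum(ts$density * ts$specific_heat *
              (sim$final$values - sim$config$initial_temperature) * w)
  expect_lt(abs(dH - sim$energy_deposited_J) / sim$energy_deposited_J, 0.005)
})

test_that("peak temperature is non-decreasing under constant heating", {
  sim <- adiabatic_sim()
  expect_false(is.unsorted(sim$step_log$peak_C))
})

test_that("dirichlet mode holds the fiber wall at 91 C throughout", {
  cfg <- sim_config(grid_extent = c(20, 20, 20), grid_spacing = 1,
                    source = fiber_source(mode = "dirichlet_wall"),
                    duration_s = 10)
  sim <- simulate_fla(cfg, accumulate_damage = FALSE)
  expect_true(all(abs(sim$step_log$peak_C - 91) < 1e-8))
  st <- assemble_source(cfg$grid, cfg$source)
  expect_true(all(abs(sim$final$values[st$clamped_nodes] - 364.15) < 1e-8))
})

test_that("the iterative solver matches a direct sparse solve", {
  cfg <- sim_config(grid_extent = c(10, 10, 10), grid_spacing = 1, duration_s = 5,
                    source = fiber_source(diffuser_length = 4, capsule_radius = 2))
  st <- assemble_source(cfg$grid, cfg$source)
  sys <- littsim:::assemble_bioheat_system(cfg$grid, cfg$tissue, st, cfg$dt)
  set.seed(11)
  b <- stats::rnorm(sys$n)
  x_direct <- as.numeric(Matrix::solve(sys$A, b))
  x_gmres <- littsim:::gmres_solve(sys$A, b, rep(0, sys$n), sys$diag_A,
                                   tol = 1e-10)$x
  expect_lt(max(abs(x_direct - x_gmres)) / max(abs(x_direct)), 1e-6)
  # an unreachable tolerance with a tiny iteration budget raises a solver error
  expect_error(
    littsim:::gmres_solve(sys$A, b, rep(0, sys$n), sys$diag_A,
                          tol = 1e-14, restart = 2L, max_restarts = 1L),
    class = "littsim_solver_error"
  )
})

test_that("Crank-Nicolson stays close to backward Euler on a smooth run", {
  base <- list(grid_extent = c(20, 20, 20), grid_spacing = 2, duration_s = 10)
  sim_be <- simulate_fla(do.call(sim_config, base), accumulate_damage = FALSE)
  sim_cn <- simulate_fla(do.call(sim_config, c(base, time_integration = "crank_nicolson")),
                         accumulate_damage = FALSE)
  rise_be <- max(sim_be$final$values) - 310.15
  rise_cn <- max(sim_cn$final$values) - 310.15
  expect_lt(abs(rise_be - rise_cn) / rise_be, 0.05)
})

test_that("histories start uniform at t = 0 and stream consistently", {
  sim <- adiabatic_sim()
  h <- sim$history
  expect_equal(h$times[1], 0)
  expect_true(all(diff(h$times) > 0))
  expect_true(all(h$fields[[1]] == sim$config$initial_temperature))
  # streamed damage equals damage accumulated from the stored history
  d_hist <- accumulate_damage(h, sim$config$kinetics)
  expect_equal(max(abs(d_hist$omega$values - sim$damage$omega$values)), 0)
  # the callback sees exactly the stored frames
  seen <- new.env(); seen$n <- 0L; seen$max_dev <- 0
  cfg <- sim$config
  invisible(simulate_fla(cfg, keep_history = FALSE, accumulate_damage = FALSE,
                         callback = function(field, t) {
                           seen$n <- seen$n + 1L
                           i <- which(abs(h$times - t) < 1e-9)
                           seen$max_dev <- max(seen$max_dev,
                                               max(abs(field$values - h$fields[[i]])))
                         }))
  expect_equal(seen$n, length(h$times) - 1L)
  expect_lt(seen$max_dev, 1e-12)
  # malformed histories are rejected
  g <- build_grid(c(2, 2, 2), 2)
  expect_error(temperature_history(g, c(0, 1, 1), rep(list(rep(310, 8)), 3)),
               class = "littsim_validation_error")
  expect_error(temperature_history(g, c(1, 2), rep(list(rep(310, 8)), 2)),
               class = "littsim_validation_error")
})
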