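test_that("fixtures are deterministic for a given seed", {
  a <- generate_fixture("gaussian_blob", extent = c(10, 10, 10), spacing = 1,
                        noise_sd = 1, seed = 5)
  b <- generate_fixture("gaussian_blob", extent = c(10, 10, 10), spacing = 1,
                        noise_sd = 1, seed = 5)
  c <- generate_fixture("gaussian_blob", extent = c(10, 10, 10), spacing = 1,
                        noise_sd = 1, seed = 6)
  expect_identical(a$field$values, b$field$values)
  expect_false(identical(a$field$values, c$field$values))
  # noise generation must not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123)
  invisible(generate_fixture("uniform", noise_sd = 1, seed = 1,
                             extent = c(4, 4, 4), spacing = 2))
  expect_identical(stats::runif(1), before)
})

test_that("fixture truths match their closed forms", {
  fx <- generate_fixture("radial_linear")
  expect_equal(fx$true_isolevel_volume_cc(43), 4 / 3 * pi * 8^3 / 1000)
  expect_equal(fx$true_isolevel_volume_cc(91), 0)
  expect_error(generate_fixture("radial_linear", slope_C_per_mm = 1),
               class = "littsim_validation_error")

  gb <- generate_fixture("gaussian_blob", sigma_mm = 5, amplitude_C = 54)
  lv <- 60
  r2 <- -2 * 25 * log((lv - 37) / 54)
  expect_equal(gb$true_isolevel_volume_cc(lv), 4 / 3 * pi * r2^1.5 / 1000)
  # and the measured volume agrees with the truth
  expect_rel_equal(isolevel_volume(gb$field, lv),
                   gb$true_isolevel_volume_cc(lv), 0.02)

  expect_error(generate_fixture("voronoi"))   # unknown kind
})

test_that("perfusion-decay history matches its analytic descriptors", {
  fx <- generate_fixture("perfusion_decay_history")
  h <- fx$history
  expect_equal(h$times[1], 0)
  expect_equal(kelvin_to_celsius(h$fields[[1]][1]), 45)
  t <- 30
  i <- which(h$times == t)
  expect_equal(kelvin_to_celsius(h$fields[[i]][1]), fx$true_temperature_C(t),
               tolerance = 1e-12)
  # trapezoidal damage over the sampled history vs adaptive quadrature
  kin <- kinetic_parameters()
  om <- accumulate_damage(h, kin)$omega$values[1]
  expect_rel_equal(om, fx$true_omega(kin), 1e-4)
})
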