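test_that("constant-temperature damage equals the closed form exactly", {
  kin_pub <- kinetic_parameters(gas_constant = 8.314)
  for (case in list(list(temp = 50, approx = 0.086, tol = 0.01),
                    list(temp = 91, approx = 8.0, tol = 0.02))) {
    d <- accumulate_damage(constant_history(case$temp), kin_pub)
    got <- d$omega$values[1]
    expect_equal(got, omega_constant(case$temp, 75, kin_pub), tolerance = 1e-12)
    expect_equal(got, case$approx, tolerance = case$tol)
  }
  # zero exposure: omega identically zero
  g <- build_grid(c(2, 2, 2), 2)
  h0 <- temperature_history(g, 0, list(rep(310.15, 8)))
  expect_true(all(accumulate_damage(h0, kin_pub)$omega$values == 0))
})

test_that("damage is additive over concatenated histories and monotone in heat", {
  kin <- kinetic_parameters()
  g <- build_grid(c(2, 2, 2), 2)
  set.seed(3)
  for (rep_i in 1:5) {
    times <- c(0, sort(stats::runif(8, 1, 74)), 75)
    temps <- stats::runif(10, 40, 95)
    fields <- lapply(temps, function(tc) rep(celsius_to_kelvin(tc), 8))
    whole <- accumulate_damage(temperature_history(g, times, fields), kin)
    cut <- 5
    part1 <- accumulate_damage(
      temperature_history(g, times[1:cut], fields[1:cut]), kin)
    part2 <- accumulate_damage(
      temperature_history(g, times[cut:10] - times[cut], fields[cut:10]), kin)
    expect_equal(whole$omega$values[1],
                 part1$omega$values[1] + part2$omega$values[1],
                 tolerance = 1e-12)
    # a pointwise-hotter history never accumulates less damage
    hotter <- accumulate_damage(
      temperature_history(g, times, lapply(fields, function(f) f + 2)), kin)
    expect_gt(hotter$omega$values[1], whole$omega$values[1])
  }
})

test_that("damage fraction maps omega to destroyed concentration", {
  expect_equal(damage_fraction(1), 0.632, tolerance = 5e-4)
  expect_equal(damage_fraction(0), 0)
  expect_equal(damage_fraction(4.6), 0.99, tolerance = 1e-3)
  expect_error(damage_fraction(-0.1), class = "littsim_validation_error")
  # strictly increasing
  om <- seq(0, 10, by = 0.5)
  expect_true(all(diff(damage_fraction(om)) > 0))
  # works on fields
  g <- build_grid(c(2, 2, 2), 2)
  f <- scalar_field(g, rep(1, 8), unit = "dimensionless")
  expect_equal(damage_fraction(f)$values[1], 1 - exp(-1))
})

test_that("threshold temperature closed form matches numeric inversion", {
  # numeric oracle: root of omega(T) = 1 for a constant hold
  numeric_threshold <- function(duration, kin) {
    uniroot(function(Tk) {
      kin$frequency_factor * duration *
        exp(-kin$activation_energy / (kin$gas_constant * Tk)) - 1
    }, c(280, 500), tol = 1e-10)$root
  }
  for (dur in c(10, 75, 300, 1200)) {
    for (kin in list(kinetic_parameters(),
                     kinetic_parameters(frequency_factor = 4.442e15),
                     kinetic_parameters(gas_constant = 8.314))) {
      expect_lt(abs(threshold_temperature(dur, kin) - numeric_threshold(dur, kin)),
                0.01)
    }
  }
  expect_error(
    threshold_temperature(50, kinetic_parameters(frequency_factor = 0.01)),
    class = "littsim_validation_error"
  )
})

test_that("frequency-factor calibration inverts the threshold relation", {
  # put the 75 s threshold at 50 C
  af <- calibrate_frequency_factor(75, celsius_to_kelvin(50),
                                   1.084e5, 8.314)
  expect_equal(af, 4.44e15, tolerance = 1e-2)
  kin <- kinetic_parameters(frequency_factor = af, gas_constant = 8.314)
  expect_equal(kelvin_to_celsius(threshold_temperature(75, kin)), 50,
               tolerance = 1e-9)
  # roundtrip the other way: the published constants' own threshold
  kin_pub <- kinetic_parameters(gas_constant = 8.314)
  t_star <- threshold_temperature(75, kin_pub)
  expect_equal(calibrate_frequency_factor(75, t_star, 1.084e5, 8.314),
               3.8e14, tolerance = 1e-9)
})

test_that("CEM43 dose reproduces the standard closed forms", {
  constant_df <- function(temp_C, minutes) {
    data.frame(time_s = c(0, minutes * 60), temperature_C = c(temp_C, temp_C))
  }
  expect_equal(cem43(constant_df(43, 10)), 10)
  expect_equal(cem43(constant_df(44, 10)), 20)          # 10 * 0.5^-1
  expect_lt(cem43(constant_df(37, 60)), 1)              # 0.25^6 factor
  expect_equal(cem43(constant_df(37, 60)), 60 * 0.25^6, tolerance = 1e-12)
  expect_error(cem43(constant_df(43, 10), r_above = 1.2),
               class = "littsim_validation_error")
  expect_error(cem43(constant_df(43, 10), r_below = 0),
               class = "littsim_validation_error")
  # history method agrees with the single-point arithmetic
  dose <- cem43(constant_history(44, tau = 600))
  expect_equal(dose$values[1], 20, tolerance = 1e-12)
  expect_equal(dose$unit, "minutes")
})

test_that("tabulated time-temperature records accumulate damage cumulatively", {
  kin <- kinetic_parameters()
  tab <- data.frame(time_s = seq(0, 75, by = 0.5), temperature_C = 91)
  out <- accumulate_damage(tab, kin)
  expect_equal(nrow(out), 151)
  expect_equal(out$omega[1], 0)
  expect_equal(out$omega[151], omega_constant(91, 75, kin), tolerance = 1e-12)
  expect_true(all(diff(out$omega) > 0))
  expect_equal(out$damage_fraction, 1 - exp(-out$omega))
  expect_error(accumulate_damage(data.frame(t = 1, temp = 2), kin),
               class = "littsim_validation_error")
})
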