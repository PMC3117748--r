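test_that("iso-level volumes match closed forms on synthetic fields", {
  # uniform body temperature: nothing above 43 C
  fx_u <- generate_fixture("uniform", extent = c(10, 10, 10), spacing = 1)
  expect_equal(isolevel_volume(fx_u$field, 43), 0)
  expect_equal(isolevel_volume(fx_u$field, 20), 1)   # whole 1 cc domain

  # spherical 91 - 6 r field: 43 C level is an 8 mm sphere, 2.145 cc
  fx <- generate_fixture("radial_linear")
  truth <- fx$true_isolevel_volume_cc(43)
  expect_equal(truth, 4 / 3 * pi * 8^3 / 1000, tolerance = 1e-12)
  expect_rel_equal(isolevel_volume(fx$field, 43), truth, 0.02)
  expect_rel_equal(isolevel_volume(fx$field, 43, correct_interface = FALSE),
                   truth, 0.02)

  # error shrinks under grid refinement
  err_at <- function(h) {
    f <- generate_fixture("radial_linear", spacing = h)
    abs(isolevel_volume(f$field, 43) - truth)
  }
  expect_lt(err_at(0.5), err_at(1))
})

test_that("iso-level volume is exact for a node-aligned planar interface", {
  g <- build_grid(c(10, 10, 10), 1)
  x <- node_coordinates(g)[, 1]
  f <- scalar_field(g, celsius_to_kelvin(91 - 6 * x))   # 43 C exactly at x = 8
  expect_equal(isolevel_volume(f, 43), 0.8, tolerance = 1e-12)  # 8x10x10 mm^3
})

test_that("iso-level volume is monotone non-increasing in the level", {
  fx <- generate_fixture("gaussian_blob", extent = c(30, 30, 30), spacing = 1,
                         noise_sd = 0.5, seed = 9)
  vols <- vapply(seq(38, 80, by = 3),
                 function(lv) isolevel_volume(fx$field, lv), numeric(1))
  expect_true(all(diff(vols) <= 0))
  vols_raw <- vapply(seq(38, 80, by = 3),
                     function(lv) isolevel_volume(fx$field, lv, FALSE), numeric(1))
  expect_true(all(diff(vols_raw) <= 0))
})

test_that("iso-damage volumes behave like iso-level volumes on the omega field", {
  g <- build_grid(c(30, 20, 20), 0.5)
  zero <- damage_field(scalar_field(g, rep(0, n_nodes(g)), unit = "dimensionless"),
                       tau = 75, kinetics = kinetic_parameters())
  expect_equal(isodamage_volume(zero), 0)

  # constant 91 C inside the capsule for 75 s: omega ~ 8 inside, ~0 outside,
  # so the omega >= 1 region is the capsule itself
  src <- fiber_source(axis_origin = c(10, 10, 10))
  mask <- capsule_mask(g, src)$values == 1
  temps <- ifelse(mask, celsius_to_kelvin(91), celsius_to_kelvin(37))
  hist <- temperature_history(g, c(0, 75), list(temps, temps))
  d <- accumulate_damage(hist, kinetic_parameters())
  expect_gt(max(d$omega$values), 7)
  cap_cc <- (pi * 4.4^2 * 10 + 4 / 3 * pi * 4.4^3) / 1000
  # the omega field is a sharp step here, so compare node counting (the
  # trilinear correction would smear the jump by design)
  expect_rel_equal(isodamage_volume(d, 1, correct_interface = FALSE), cap_cc, 0.05)
  expect_lte(isodamage_volume(d, 1), isodamage_volume(d, 0.5))
})

test_that("lesion axes distinguish spherical from fiber-elongated lesions", {
  fx <- generate_fixture("gaussian_blob")
  ax <- lesion_axes(fx$field, 50)
  expect_false(ax$prolate)
  expect_equal(ax$axial_mm, ax$perp1_mm, tolerance = 1e-9)
  expect_equal(ax$axial_mm, ax$perp2_mm, tolerance = 1e-9)

  # empty super-level set: a signal, not an error
  empty <- lesion_axes(fx$field, 200)
  expect_true(empty$empty)
  expect_true(is.na(empty$axial_mm))

  # simulated capsule-mode lesion: prolate along the fiber
  sim <- adiabatic_sim()
  ax_sim <- lesion_axes(sim$final, 43, sim$config$source)
  expect_true(ax_sim$prolate)
  expect_gte(ax_sim$axial_mm, sim$config$source$diffuser_length)
})

test_that("lesion summaries tabulate volumes and shape per level", {
  sim <- adiabatic_sim()
  ls <- lesion_summary(sim$final, c(43, 45, 50), axis = sim$config$source)
  expect_s3_class(ls, "tbl_df")
  expect_equal(ls$level, c(43, 45, 50))
  expect_true(all(diff(ls$volume_cc) <= 0))
  expect_equal(ls$volume_mm3, ls$volume_cc * 1000)
})

test_that("cohort statistics reproduce hand-computed mean and sample SD", {
  # independent arithmetic oracle
  manual <- function(x) {
    m <- sum(x) / length(x)
    list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
  }
  tab <- rat_necrosis_volumes()
  expect_equal(nrow(tab), 10)
  for (col in c("mri_cc", "histology_cc")) {
    got <- cohort_stats(tab[[col]])
    want <- manual(tab[[col]])
    expect_equal(got$mean_cc, want$mean, tolerance = 1e-12)
    expect_equal(got$sd_cc, want$sd, tolerance = 1e-12)
  }
  three <- c(0.9, 1.0, 1.1)
  got3 <- cohort_stats(three)
  expect_equal(got3$mean_cc, 1.0)
  expect_equal(got3$sd_cc, 0.1, tolerance = 1e-12)
  expect_equal(cohort_stats(c(1, 1, 1))$sd_cc, 0)
  expect_error(cohort_stats(1), class = "littsim_validation_error")
  expect_error(cohort_stats(c(1, -1)), class = "littsim_validation_error")
})

test_that("paired correlation is Pearson's product-moment coefficient", {
  x <- c(1, 2, 3, 5)
  expect_equal(paired_correlation(x, x), 1)
  expect_equal(paired_correlation(x, 10 - x), -1)
  # manual formula oracle on the packaged cohort
  tab <- rat_necrosis_volumes()
  a <- tab$mri_cc; b <- tab$histology_cc
  manual_r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  r <- paired_correlation(a, b)
  expect_equal(r, manual_r, tolerance = 1e-12)
  expect_gt(r, 0.87); expect_lt(r, 0.88)
  expect_error(paired_correlation(c(1, 1, 1), x[1:3]),
               class = "littsim_validation_error")
  expect_error(paired_correlation(1:2, 1:2), class = "littsim_validation_error")
})

test_that("energy-to-volume ratios are simple and validated", {
  expect_equal(energy_volume_ratio(3260, 4.5), 724.4, tolerance = 1e-3)
  expect_equal(energy_volume_ratio(4014, 2.8), 1433.6, tolerance = 1e-3)
  expect_equal(energy_volume_ratio(5 * 75, 1), 375)
  expect_error(energy_volume_ratio(100, 0), class = "littsim_validation_error")
  expect_error(energy_volume_ratio(100, -1), class = "littsim_validation_error")
})
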