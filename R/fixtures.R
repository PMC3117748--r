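#' Generate synthetic fields and histories with closed-form descriptors
#'
#' Deterministic synthetic stand-ins used to verify the volumetric and
#' damage machinery against closed forms:
#'
#' * `"radial_linear"`: spherically symmetric temperature field
#'   `T(r) = peak_C + slope_C_per_mm * r` around `center`. The true volume
#'   above a level `L` is the sphere `4/3 pi r*^3` with
#'   `r* = (peak_C - L) / |slope|` (exact while the sphere fits in the
#'   domain), returned as `true_isolevel_volume_cc`.
#' * `"gaussian_blob"`: `T(r) = base_C + amplitude_C exp(-r^2 / (2 sigma^2))`,
#'   with the analogous closed-form iso-volume.
#' * `"uniform"`: constant field; any level above it has true volume 0, any
#'   level at or below it the full domain volume.
#' * `"perfusion_decay_history"`: a spatially uniform exponential
#'   temperature decay `T(t) = blood_C + (initial_C - blood_C) exp(-w t)` on
#'   a tiny grid, with `true_temperature_C(t)` and `true_omega(kinetics)`
#'   (adaptive quadrature of the Arrhenius integral) descriptors.
#'
#' Optional Gaussian node noise (`noise_sd`, degrees C) is generated from
#' `seed` without disturbing the caller's RNG state; the same seed always
#' reproduces the same output.
#'
#' @param kind fixture kind, see above.
#' @param extent,spacing grid geometry (mm). Defaults suit each kind.
#' @param peak_C,slope_C_per_mm,center `"radial_linear"` parameters.
#' @param base_C,amplitude_C,sigma_mm `"gaussian_blob"` parameters.
#' @param value_C `"uniform"` value.
#' @param initial_C,blood_C,omega_vol,duration_s,dt_s
#'   `"perfusion_decay_history"` parameters (`omega_vol` in 1/s).
#' @param noise_sd standard deviation of additive node noise (degrees C).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return a list of class `litt_fixture`: `kind`, `params`, and either
#'   `field` (a `scalar_field`) with `true_isolevel_volume_cc(level)`, or
#'   `history` (a [temperature_history()]) with `true_temperature_C(t)` and
#'   `true_omega(kinetics)`.
#' @examples
#' fx <- generate_fixture("radial_linear")
#' fx$true_isolevel_volume_cc(43)   # 2.145 cc
#' @export
generate_fixture <- function(kind = c("radial_linear", "gaussian_blob",
                                      "uniform", "perfusion_decay_history"),
                             extent = NULL, spacing = NULL,
                             peak_C = 91, slope_C_per_mm = -6, center = NULL,
                             base_C = 37, amplitude_C = 54, sigma_mm = 5,
                             value_C = 37,
                             initial_C = 45, blood_C = 37,
                             omega_vol = 1.665e-3, duration_s = 75, dt_s = 0.5,
                             noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  check_number(noise_sd, "noise_sd", lower = 0)

  noisy <- function(values_C) {
    if (noise_sd > 0) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
              else suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
      set.seed(as.integer(seed))
      values_C <- values_C + stats::rnorm(length(values_C), sd = noise_sd)
    }
    values_C
  }

  if (kind == "perfusion_decay_history") {
    extent <- extent %||% c(4, 4, 4)
    spacing <- spacing %||% 2
    grid <- build_grid(extent, spacing)
    times <- seq(0, duration_s, by = dt_s)
    temp_C <- function(t) blood_C + (initial_C - blood_C) * exp(-omega_vol * t)
    fields <- lapply(times, function(t) {
      rep(celsius_to_kelvin(temp_C(t)), n_nodes(grid))
    })
    return(structure(list(
      kind = kind,
      history = temperature_history(grid, times, fields),
      true_temperature_C = temp_C,
      true_omega = function(kinetics) {
        stopifnot(inherits(kinetics, "kinetic_parameters"))
        kinetics$frequency_factor * stats::integrate(
          function(t) arrhenius_rate(celsius_to_kelvin(temp_C(t)), kinetics),
          0, duration_s, rel.tol = 1e-10)$value
      },
      params = list(initial_C = initial_C, blood_C = blood_C,
                    omega_vol = omega_vol, duration_s = duration_s, dt_s = dt_s),
      seed = seed
    ), class = "litt_fixture"))
  }

  extent <- extent %||% c(40, 40, 40)
  spacing <- spacing %||% 0.5
  grid <- build_grid(extent, spacing)
  center <- center %||% (extent / 2)
  coords <- node_coordinates(grid)
  r <- sqrt(rowSums(sweep(coords, 2, center)^2))
  domain_cc <- prod(extent) / 1000

  if (kind == "radial_linear") {
    if (slope_C_per_mm >= 0) {
      stop_validation("`slope_C_per_mm` must be negative for a radial_linear fixture.")
    }
    vals <- peak_C + slope_C_per_mm * r
    truth <- function(level) {
      r_star <- (peak_C - level) / abs(slope_C_per_mm)
      if (r_star <= 0) 0 else 4 / 3 * pi * r_star^3 / 1000
    }
  } else if (kind == "gaussian_blob") {
    check_number(sigma_mm, "sigma_mm", lower = 0, strict_lower = TRUE)
    check_number(amplitude_C, "amplitude_C", lower = 0, strict_lower = TRUE)
    vals <- base_C + amplitude_C * exp(-r^2 / (2 * sigma_mm^2))
    truth <- function(level) {
      if (level <= base_C) return(domain_cc)
      if (level > base_C + amplitude_C) return(0)
      r2 <- -2 * sigma_mm^2 * log((level - base_C) / amplitude_C)
      4 / 3 * pi * r2^1.5 / 1000
    }
  } else { # uniform
    vals <- rep(value_C, length(r))
    truth <- function(level) if (level <= value_C) domain_cc else 0
  }

  structure(list(
    kind = kind,
    field = scalar_field(grid, celsius_to_kelvin(noisy(vals)), unit = "kelvin"),
    true_isolevel_volume_cc = truth,
    params = list(peak_C = peak_C, slope_C_per_mm = slope_C_per_mm,
                  center = center, base_C = base_C, amplitude_C = amplitude_C,
                  sigma_mm = sigma_mm, value_C = value_C,
                  noise_sd = noise_sd),
    seed = seed
  ), class = "litt_fixture")
}

#' @export
print.litt_fixture <- function(x, ...) {
  cat(sprintf("<litt_fixture> kind %s (seed %s)\n", x$kind, x$seed))
  invisible(x)
}
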