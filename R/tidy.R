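#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a simulation into its per-step log
#'
#' @param x an `fla_simulation`.
#' @param ... unused.
#' @return a tibble with one row per time step: `step`, `phase`, `time_s`,
#'   `peak_C`, `mean_C`, solver `iterations` and `residual`.
#' @method tidy fla_simulation
#' @export
tidy.fla_simulation <- function(x, ...) x$step_log

#' One-row summary of a simulation
#'
#' @param x an `fla_simulation`.
#' @param ... unused.
#' @return a tibble with the grid size, source mode, peak temperature,
#'   deposited energy, and (when damage was accumulated) the
#'   necrosis-border volume at damage integral 1.
#' @method glance fla_simulation
#' @export
glance.fla_simulation <- function(x, ...) {
  tibble(
    n_nodes = n_nodes(x$config$grid),
    spacing_mm = x$config$grid$spacing,
    mode = x$source_term$mode,
    duration_s = x$config$duration,
    cooldown_s = x$config$cooldown_duration,
    peak_C = max(x$step_log$peak_C),
    energy_deposited_J = x$energy_deposited_J,
    necrosis_volume_cc = if (!is.null(x$damage)) {
      isodamage_volume(x$damage, 1)
    } else NA_real_
  )
}

#' One-row summary of a damage field
#'
#' @param x a [damage_field()].
#' @param ... unused.
#' @return a tibble with the exposure time, the maximum damage integral and
#'   destroyed fraction, and the necrosis-border volume.
#' @method glance damage_field
#' @export
glance.damage_field <- function(x, ...) {
  mx <- max(x$omega$values)
  tibble(
    tau_s = x$tau,
    max_omega = mx,
    max_damage_fraction = damage_fraction(mx),
    necrosis_volume_cc = isodamage_volume(x, 1)
  )
}

#' Convert a scalar field to a tibble of node records
#'
#' @param x a `scalar_field`.
#' @param ... unused.
#' @return a tibble with columns `x_mm`, `y_mm`, `z_mm`, `value` (and
#'   `value_C` for kelvin fields).
#' @method tidy scalar_field
#' @export
tidy.scalar_field <- function(x, ...) {
  coords <- node_coordinates(x$grid)
  out <- tibble(
    x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3],
    value = as.vector(x$values)
  )
  if (x$unit == "kelvin") out$value_C <- kelvin_to_celsius(out$value)
  out
}
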