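## Arrhenius thermal-damage kinetics.
##
## Tissue coagulation is modelled as a first-order unimolecular rate process:
## the damage integral
##   Omega(tau) = A_f * int_0^tau exp(-E_a / (R T(t))) dt
## is the log-ratio of the initial to the remaining concentration of native
## (undamaged) molecules, so the destroyed fraction is 1 - exp(-Omega).
## Omega = 1 (63.2% destroyed) is taken as the coagulative-necrosis border.

## Temperature-dependent rate factor exp(-E_a / (R T)); T in kelvin.
arrhenius_rate <- function(T_kelvin, kinetics) {
  exp(-kinetics$activation_energy /
        (kinetics$gas_constant * T_kelvin))
}

#' Damage field container
#'
#' @param omega a `scalar_field` of non-negative damage-integral values.
#' @param tau exposure time covered by the integral (s).
#' @param kinetics the [kinetic_parameters()] used.
#' @return an object of class `damage_field`.
#' @export
damage_field <- function(omega, tau, kinetics) {
  stopifnot(inherits(omega, "scalar_field"),
            inherits(kinetics, "kinetic_parameters"))
  if (any(omega$values < 0)) {
    stop_validation("damage integral values must be non-negative.")
  }
  check_number(tau, "tau", lower = 0)
  structure(list(omega = omega, tau = tau, kinetics = kinetics),
            class = "damage_field")
}

#' @export
print.damage_field <- function(x, ...) {
  cat(sprintf("<damage_field> tau = %g s, max omega %.4g, damaged (omega >= 1) nodes: %d\n",
              x$tau, max(x$omega$values), sum(x$omega$values >= 1)))
  invisible(x)
}

#' Accumulate the Arrhenius damage integral over a temperature history
#'
#' Computes the node-wise damage integral
#' `Omega = A_f * integral exp(-E_a / (R T(t))) dt` by the trapezoidal rule
#' over the history's time points. On a constant-temperature history this is
#' exact, equalling `A_f * tau * exp(-E_a / (R T))`. The integral is additive
#' over concatenated histories that share their junction frame.
#'
#' For grids too large to store as a history, [simulate_fla()] accumulates
#' the same trapezoidal integral in a streaming fashion during the run.
#'
#' @param history a [temperature_history()], or a data frame with columns
#'   `time_s` and `temperature_C` (a single-point measurement series, e.g.
#'   read from CSV).
#' @param kinetics a [kinetic_parameters()] object.
#' @param ... unused.
#' @return for a history: a [damage_field()]. For a data frame: a tibble with
#'   columns `time_s`, `omega` (cumulative), and `damage_fraction`.
#' @examples
#' # constant 91 C for 75 s
#' g <- build_grid(c(2, 2, 2), 2)
#' h <- temperature_history(g, c(0, 75),
#'                          rep(list(rep(celsius_to_kelvin(91), 8)), 2))
#' max(accumulate_damage(h, kinetic_parameters())$omega$values)  # ~ 8
#' @export
accumulate_damage <- function(history, kinetics, ...) {
  UseMethod("accumulate_damage")
}

#' @export
accumulate_damage.temperature_history <- function(history, kinetics, ...) {
  stopifnot(inherits(kinetics, "kinetic_parameters"))
  times <- history$times
  if (any(diff(times) <= 0)) {
    stop_validation("history times must be strictly increasing.")
  }
  omega <- 0
  if (length(times) > 1L) {
    rate_prev <- arrhenius_rate(as.vector(history$fields[[1]]), kinetics)
    omega <- rep(0, n_nodes(history$grid))
    for (i in seq_along(times)[-1]) {
      rate_now <- arrhenius_rate(as.vector(history$fields[[i]]), kinetics)
      omega <- omega + kinetics$frequency_factor *
        (times[i] - times[i - 1]) / 2 * (rate_prev + rate_now)
      rate_prev <- rate_now
    }
  } else {
    omega <- rep(0, n_nodes(history$grid))
  }
  damage_field(scalar_field(history$grid, omega, unit = "dimensionless"),
               tau = max(times), kinetics = kinetics)
}

#' @export
accumulate_damage.data.frame <- function(history, kinetics, ...) {
  stopifnot(inherits(kinetics, "kinetic_parameters"))
  cols <- names(history)
  if (!"time_s" %in% cols || !any(c("temperature_C", "temperature_K") %in% cols)) {
    stop_validation(
      "data-frame histories need columns `time_s` and `temperature_C` (or `temperature_K`).")
  }
  t <- history$time_s
  if (length(t) < 1L || any(diff(t) <= 0)) {
    stop_validation("`time_s` must be strictly increasing.")
  }
  T_k <- if ("temperature_K" %in% cols) history$temperature_K else
    celsius_to_kelvin(history$temperature_C)
  rate <- arrhenius_rate(T_k, kinetics)
  inc <- c(0, kinetics$frequency_factor * diff(t) / 2 *
             (rate[-length(rate)] + rate[-1]))
  tibble(
    time_s = t,
    omega = cumsum(inc),
    damage_fraction = damage_fraction(cumsum(inc))
  )
}

#' @export
accumulate_damage.fla_simulation <- function(history, kinetics, ...) {
  if (is.null(history$history)) {
    stop_validation(paste0(
      "this simulation kept no temperature history; re-run with ",
      "`keep_history = TRUE`, or use the streamed `$damage` component."))
  }
  accumulate_damage(history$history, kinetics, ...)
}

#' Destroyed-concentration fraction from the damage integral
#'
#' For the first-order unimolecular damage process, the fraction of
#' molecules destroyed after accumulating damage `Omega` is
#' `1 - exp(-Omega)`; `Omega = 1` corresponds to 63.2%.
#'
#' @param omega non-negative damage integral: a numeric vector or a
#'   dimensionless `scalar_field`.
#' @return fractions in `[0, 1)`, of the same shape as the input.
#' @examples
#' damage_fraction(1)    # 0.632
#' damage_fraction(4.6)  # ~ 0.99
#' @export
damage_fraction <- function(omega) {
  if (inherits(omega, "damage_field")) omega <- omega$omega
  if (inherits(omega, "scalar_field")) {
    out <- omega
    out$values <- damage_fraction(as.vector(omega$values))
    out$unit <- "dimensionless"
    out$values <- array(out$values, dim = omega$grid$shape)
    return(out)
  }
  if (!is.numeric(omega) || any(!is.finite(omega))) {
    stop_validation("`omega` must be finite and numeric.")
  }
  if (any(omega < 0)) {
    stop_validation("`omega` must be non-negative.")
  }
  1 - exp(-omega)
}

#' Constant-temperature damage threshold
#'
#' The constant hold temperature at which the damage integral reaches 1
#' after `duration` seconds: `T* = E_a / (R * log(A_f * duration))`. Below
#' `A_f * duration = 1` no finite temperature reaches the threshold and an
#' error is raised.
#'
#' @param duration exposure time (s).
#' @param kinetics a [kinetic_parameters()] object.
#' @return threshold temperature (K). Convert with [kelvin_to_celsius()].
#' @examples
#' kelvin_to_celsius(threshold_temperature(75, kinetic_parameters()))  # ~ 71 C
#' @export
threshold_temperature <- function(duration, kinetics) {
  stopifnot(inherits(kinetics, "kinetic_parameters"))
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  prod_at <- kinetics$frequency_factor * duration
  if (prod_at <= 1) {
    stop_validation(sprintf(
      "no solution: A_f * duration = %g <= 1, so omega cannot reach 1 at any temperature.",
      prod_at))
  }
  kinetics$activation_energy / (kinetics$gas_constant * log(prod_at))
}

#' Calibrate the frequency factor to a prescribed damage threshold
#'
#' Inverse of [threshold_temperature()]: returns the frequency factor `A_f`
#' for which a constant hold at `threshold_T` for `duration` seconds yields
#' exactly `Omega = 1`:  `A_f = exp(E_a / (R * threshold_T)) / duration`.
#' Useful for reconciling published kinetic constants with an independently
#' reported threshold temperature.
#'
#' @param duration exposure time (s).
#' @param threshold_T target threshold temperature (K).
#' @param activation_energy `E_a` (J/mol).
#' @param gas_constant `R` (J/mol/K).
#' @return frequency factor (1/s).
#' @examples
#' # A_f that puts the 75 s threshold at 50 C:
#' calibrate_frequency_factor(75, celsius_to_kelvin(50))  # ~ 4.4e15
#' @export
calibrate_frequency_factor <- function(duration, threshold_T,
                                       activation_energy = 1.084e5,
                                       gas_constant = 8.314462618) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(threshold_T, "threshold_T", lower = 0, strict_lower = TRUE)
  check_number(activation_energy, "activation_energy", lower = 0, strict_lower = TRUE)
  check_number(gas_constant, "gas_constant", lower = 0, strict_lower = TRUE)
  exp(activation_energy / (gas_constant * threshold_T)) / duration
}

#' Cumulative equivalent minutes at 43 C (CEM43)
#'
#' The standard thermal-dose normalisation of a temperature history:
#' `CEM43 = sum dt_min * Rf^(43 - T_C)` with `Rf = r_above` for intervals at
#' or above 43 C and `r_below` otherwise (classic factors 0.5 / 0.25). Each
#' interval uses its mean temperature; constant-temperature histories are
#' treated exactly.
#'
#' @param history a [temperature_history()] or a data frame with columns
#'   `time_s` and `temperature_C` (or `temperature_K`).
#' @param r_below,r_above dose-rate factors below/above the 43 C breakpoint;
#'   both must lie strictly between 0 and 1.
#' @param ... unused.
#' @return for a history: a `scalar_field` (unit `"minutes"`) of node-wise
#'   CEM43; for a data frame: a single number (minutes).
#' @examples
#' h <- data.frame(time_s = c(0, 600), temperature_C = c(44, 44))
#' cem43(h)  # 20 equivalent minutes
#' @export
cem43 <- function(history, r_below = 0.25, r_above = 0.5, ...) {
  check_number(r_below, "r_below", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(r_above, "r_above", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  UseMethod("cem43")
}

cem43_increment <- function(T_mean_C, dt_s, r_below, r_above) {
  rf <- ifelse(T_mean_C >= 43, r_above, r_below)
  dt_s / 60 * rf^(43 - T_mean_C)
}

#' @export
cem43.temperature_history <- function(history, r_below = 0.25, r_above = 0.5,
                                      ...) {
  times <- history$times
  dose <- rep(0, n_nodes(history$grid))
  if (length(times) > 1L) {
    for (i in seq_along(times)[-1]) {
      T_mean <- kelvin_to_celsius(
        (as.vector(history$fields[[i - 1]]) + as.vector(history$fields[[i]])) / 2)
      dose <- dose + cem43_increment(T_mean, times[i] - times[i - 1],
                                     r_below, r_above)
    }
  }
  scalar_field(history$grid, dose, unit = "minutes")
}

#' @export
cem43.data.frame <- function(history, r_below = 0.25, r_above = 0.5, ...) {
  cols <- names(history)
  if (!"time_s" %in% cols || !any(c("temperature_C", "temperature_K") %in% cols)) {
    stop_validation(
      "data-frame histories need columns `time_s` and `temperature_C` (or `temperature_K`).")
  }
  t <- history$time_s
  T_c <- if ("temperature_K" %in% cols) kelvin_to_celsius(history$temperature_K) else
    history$temperature_C
  if (length(t) < 2L || any(diff(t) <= 0)) {
    stop_validation("`time_s` must be strictly increasing with at least two points.")
  }
  T_mean <- (T_c[-length(T_c)] + T_c[-1]) / 2
  sum(cem43_increment(T_mean, diff(t), r_below, r_above))
}
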