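#' Simulation configuration
#'
#' Bundles everything a run needs: domain and grid, tissue and kinetic
#' constants, fiber source, and solver settings. The defaults reproduce the
#' package's reference ablation protocol: a 70 x 70 x 20 mm homogeneous block
#' at 0.5 mm spacing, 37 C initial temperature, a centred 10 mm diffusing
#' fiber delivering 5 W for 75 s, backward-Euler steps of 0.5 s, and an
#' iterative-solver relative tolerance of 1e-3.
#'
#' @param grid_extent domain size (mm, 3-vector).
#' @param grid_spacing node spacing (mm).
#' @param tissue a [tissue_properties()] object.
#' @param source a [fiber_source()] object; a `NULL` `axis_origin` is centred
#'   in the domain.
#' @param kinetics a [kinetic_parameters()] object (used when damage is
#'   accumulated alongside the simulation).
#' @param initial_temperature_C uniform starting temperature (C). Default 37.
#' @param duration_s heating time with the source active (s). Default 75.
#' @param dt_s time step (s). Default 0.5. Must divide `duration_s` (and
#'   `cooldown_duration_s`) evenly.
#' @param linear_solver_tolerance relative residual-reduction tolerance of
#'   the iterative linear solver. Default 1e-3.
#' @param cooldown_duration_s extra simulated time after the source is
#'   switched off (s). Default 0: lesion metrics are reported at the end of
#'   heating.
#' @param time_integration `"backward_euler"` (default, unconditionally
#'   stable) or `"crank_nicolson"`.
#' @param linear_solver `"auto"` (direct sparse factorisation for small
#'   grids, iterative otherwise), `"iterative"`, or `"direct"`.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(grid_spacing = 2)
#' cfg$grid$shape
#' @export
sim_config <- function(grid_extent = c(70, 70, 20),
                       grid_spacing = 0.5,
                       tissue = tissue_properties(),
                       source = fiber_source(),
                       kinetics = kinetic_parameters(),
                       initial_temperature_C = 37,
                       duration_s = 75,
                       dt_s = 0.5,
                       linear_solver_tolerance = 1e-3,
                       cooldown_duration_s = 0,
                       time_integration = c("backward_euler", "crank_nicolson"),
                       linear_solver = c("auto", "iterative", "direct")) {
  stopifnot(inherits(tissue, "tissue_properties"),
            inherits(source, "fiber_source"),
            inherits(kinetics, "kinetic_parameters"))
  time_integration <- match.arg(time_integration)
  linear_solver <- match.arg(linear_solver)
  check_number(initial_temperature_C, "initial_temperature_C",
               lower = -273.15, strict_lower = TRUE)
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(dt_s, "dt_s", lower = 0, upper = duration_s, strict_lower = TRUE)
  check_number(linear_solver_tolerance, "linear_solver_tolerance",
               lower = 0, strict_lower = TRUE)
  check_number(cooldown_duration_s, "cooldown_duration_s", lower = 0)
  for (nm in c("duration_s", "cooldown_duration_s")) {
    v <- get(nm)
    if (abs(v / dt_s - round(v / dt_s)) > 1e-8) {
      stop_validation(sprintf("`dt_s` must evenly divide `%s`.", nm))
    }
  }
  grid <- build_grid(grid_extent, grid_spacing, source)
  structure(
    list(
      grid = grid,
      tissue = tissue,
      source = resolve_fiber(source, grid$extent),
      kinetics = kinetics,
      initial_temperature = celsius_to_kelvin(initial_temperature_C),
      duration = duration_s,
      dt = dt_s,
      linear_solver_tolerance = linear_solver_tolerance,
      cooldown_duration = cooldown_duration_s,
      time_integration = time_integration,
      linear_solver = linear_solver
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  print(x$grid)
  cat(sprintf("  T0 %.2f C, heat %g s (+ cooldown %g s) at dt %g s, %s, solver %s tol %g\n",
              kelvin_to_celsius(x$initial_temperature), x$duration,
              x$cooldown_duration, x$dt, x$time_integration, x$linear_solver,
              x$linear_solver_tolerance))
  print(x$source)
  invisible(x)
}

## ---- configuration files ----------------------------------------------------

config_allowed_keys <- list(
  grid = c("extent", "spacing"),
  tissue = c("density", "specific_heat", "conductivity", "perfusion",
             "blood_temperature_C", "metabolic_heat", "blood_density",
             "blood_specific_heat"),
  source = c("axis_origin", "axis_direction", "diffuser_length",
             "core_diameter", "mode", "power", "wall_temperature_C",
             "capsule_radius", "mu_eff"),
  kinetics = c("frequency_factor", "activation_energy", "gas_constant"),
  simulation = c("initial_temperature_C", "duration_s", "dt_s",
                 "linear_solver_tolerance", "cooldown_duration_s",
                 "time_integration", "linear_solver")
)

#' Read a simulation configuration from a YAML file
#'
#' The file may contain any subset of the sections `grid`, `tissue`,
#' `source`, `kinetics`, and `simulation`; unspecified keys take the package
#' defaults (see [sim_config()]), so an empty file yields the full reference
#' configuration. Unknown sections or keys are rejected with an error rather
#' than silently ignored — a misspelt key must not silently fall back to a
#' default. All temperatures in the file are in degrees Celsius.
#'
#' @param path path to a YAML configuration file.
#' @return a [sim_config()] object.
#' @seealso [config_as_list()] for the inverse (used in run manifests).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("configuration file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    stop_validation("configuration file must be a YAML mapping.")
  }
  config_from_list(raw)
}

#' @rdname load_config
#' @param x a nested list in the layout produced by [config_as_list()].
#' @export
config_from_list <- function(x) {
  unknown_sections <- setdiff(names(x), names(config_allowed_keys))
  if (length(unknown_sections)) {
    stop_validation(sprintf(
      "unknown configuration section(s): %s (allowed: %s)",
      paste(unknown_sections, collapse = ", "),
      paste(names(config_allowed_keys), collapse = ", ")))
  }
  for (sec in names(x)) {
    unknown <- setdiff(names(x[[sec]]), config_allowed_keys[[sec]])
    if (length(unknown)) {
      stop_validation(sprintf(
        "unknown key(s) in section `%s`: %s (allowed: %s)",
        sec, paste(unknown, collapse = ", "),
        paste(config_allowed_keys[[sec]], collapse = ", ")))
    }
  }
  g <- x$grid %||% list()
  src_args <- x$source %||% list()
  if (!is.null(src_args$axis_origin)) {
    src_args$axis_origin <- as.numeric(unlist(src_args$axis_origin))
  }
  if (!is.null(src_args$axis_direction)) {
    src_args$axis_direction <- as.numeric(unlist(src_args$axis_direction))
  }
  args <- c(
    list(
      grid_extent = as.numeric(unlist(g$extent %||% c(70, 70, 20))),
      grid_spacing = g$spacing %||% 0.5,
      tissue = do.call(tissue_properties, x$tissue %||% list()),
      source = do.call(fiber_source, src_args),
      kinetics = do.call(kinetic_parameters, x$kinetics %||% list())
    ),
    x$simulation %||% list()
  )
  do.call(sim_config, args)
}

#' Serialise a configuration to a plain nested list
#'
#' The returned list round-trips through [config_from_list()] /
#' [load_config()] and fully reproduces the run (it is embedded in run
#' manifests for that purpose). Temperatures are reported in degrees Celsius.
#'
#' @param config a [sim_config()] object.
#' @return a nested list mirroring the configuration-file layout.
#' @export
config_as_list <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ts <- config$tissue
  src <- config$source
  kin <- config$kinetics
  list(
    grid = list(extent = config$grid$extent, spacing = config$grid$spacing),
    tissue = list(
      density = ts$density, specific_heat = ts$specific_heat,
      conductivity = ts$conductivity, perfusion = ts$perfusion,
      blood_temperature_C = kelvin_to_celsius(ts$blood_temperature),
      metabolic_heat = ts$metabolic_heat, blood_density = ts$blood_density,
      blood_specific_heat = ts$blood_specific_heat
    ),
    source = list(
      axis_origin = src$axis_origin, axis_direction = src$axis_direction,
      diffuser_length = src$diffuser_length, core_diameter = src$core_diameter,
      mode = src$mode, power = src$power,
      wall_temperature_C = kelvin_to_celsius(src$wall_temperature),
      capsule_radius = src$capsule_radius, mu_eff = src$mu_eff
    ),
    kinetics = list(
      frequency_factor = kin$frequency_factor,
      activation_energy = kin$activation_energy,
      gas_constant = kin$gas_constant
    ),
    simulation = list(
      initial_temperature_C = kelvin_to_celsius(config$initial_temperature),
      duration_s = config$duration, dt_s = config$dt,
      linear_solver_tolerance = config$linear_solver_tolerance,
      cooldown_duration_s = config$cooldown_duration,
      time_integration = config$time_integration,
      linear_solver = config$linear_solver
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
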