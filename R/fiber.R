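#' Cylindrical diffusing fiber source
#'
#' Describes the geometry and forcing of the interstitial laser applicator: a
#' cylindrical diffusing fiber (CDF) emitting radially along a diffuser
#' segment. Three interchangeable forcing modes are provided because the
#' spatial deposition profile of a real CDF cannot be uniquely reconstructed
#' from power and peak-temperature measurements alone:
#'
#' * `"uniform_capsule"` (reference mode): the total optical `power` is
#'   deposited uniformly inside the capsule of radius `capsule_radius` around
#'   the diffuser segment. The default radius of 4.4 mm makes the capsule
#'   volume close to 1000 mm^3, so the default 5 W corresponds to a volumetric
#'   deposition of about 5e-3 W/mm^3.
#' * `"dirichlet_wall"`: no volumetric deposition; grid nodes inside the fiber
#'   cylinder are clamped at `wall_temperature_C` (the measured fiber-wall
#'   temperature, default 91 C).
#' * `"radial_exponential"`: deposition proportional to
#'   `exp(-mu_eff * d) / max(d, core radius)` with `d` the distance to the
#'   diffuser axis, renormalised so the deposited total equals `power`;
#'   approaches a line source for large `mu_eff`.
#'
#' @param axis_origin start point of the diffuser segment (mm, 3-vector), or
#'   `NULL` (default) to centre the segment in the simulation domain along
#'   `axis_direction` when the grid is built.
#' @param axis_direction unit 3-vector along the fiber axis; normalised
#'   internally. Default along x, the longest axis of the default domain.
#' @param diffuser_length length of the diffusing segment (mm). Default 10.
#' @param core_diameter fiber core diameter (mm). Default 0.5.
#' @param mode forcing mode, see Details. Default `"uniform_capsule"`.
#' @param power total optical power (W). Default 5.
#' @param wall_temperature_C clamp temperature for `"dirichlet_wall"` (C).
#'   Default 91.
#' @param capsule_radius absorption capsule radius for `"uniform_capsule"`
#'   (mm). Default 4.4.
#' @param mu_eff effective attenuation coefficient for
#'   `"radial_exponential"` (1/mm). Default 0.5.
#' @return an object of class `fiber_source`.
#' @examples
#' fiber_source()
#' fiber_source(mode = "dirichlet_wall")
#' @export
fiber_source <- function(axis_origin = NULL,
                         axis_direction = c(1, 0, 0),
                         diffuser_length = 10,
                         core_diameter = 0.5,
                         mode = c("uniform_capsule", "dirichlet_wall",
                                  "radial_exponential"),
                         power = 5,
                         wall_temperature_C = 91,
                         capsule_radius = 4.4,
                         mu_eff = 0.5) {
  mode <- match.arg(mode)
  axis_direction <- check_vector3(axis_direction, "axis_direction")
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm < 1e-12) {
    stop_validation("`axis_direction` must be a nonzero vector.")
  }
  axis_direction <- axis_direction / nrm
  if (!is.null(axis_origin)) {
    axis_origin <- check_vector3(axis_origin, "axis_origin")
  }
  check_number(diffuser_length, "diffuser_length", lower = 0, strict_lower = TRUE)
  check_number(core_diameter, "core_diameter", lower = 0, strict_lower = TRUE)
  check_number(power, "power", lower = 0)
  check_number(wall_temperature_C, "wall_temperature_C", lower = -273.15,
               strict_lower = TRUE)
  check_number(capsule_radius, "capsule_radius", lower = core_diameter / 2)
  check_number(mu_eff, "mu_eff", lower = 0, strict_lower = TRUE)
  structure(
    list(
      axis_origin = axis_origin,
      axis_direction = axis_direction,
      diffuser_length = diffuser_length,
      core_diameter = core_diameter,
      mode = mode,
      power = power,
      wall_temperature = celsius_to_kelvin(wall_temperature_C),
      capsule_radius = capsule_radius,
      mu_eff = mu_eff
    ),
    class = "fiber_source"
  )
}

#' @export
print.fiber_source <- function(x, ...) {
  cat("<fiber_source>\n")
  org <- if (is.null(x$axis_origin)) "domain-centred" else
    paste0("(", paste(format(x$axis_origin), collapse = ", "), ") mm")
  cat(sprintf("  mode %s,  power %.3g W\n", x$mode, x$power))
  cat(sprintf("  diffuser %g mm long, core %g mm, origin %s, direction (%s)\n",
              x$diffuser_length, x$core_diameter, org,
              paste(format(x$axis_direction, digits = 3), collapse = ", ")))
  if (x$mode == "dirichlet_wall") {
    cat(sprintf("  wall temperature %.2f C\n", kelvin_to_celsius(x$wall_temperature)))
  }
  if (x$mode == "uniform_capsule") {
    cat(sprintf("  capsule radius %g mm\n", x$capsule_radius))
  }
  if (x$mode == "radial_exponential") {
    cat(sprintf("  mu_eff %g 1/mm\n", x$mu_eff))
  }
  invisible(x)
}

#' Resolve a domain-centred fiber placement
#'
#' If `axis_origin` is `NULL`, places the diffuser segment at the centre of a
#' domain of the given extent, centred along its axis direction.
#'
#' @param source a [fiber_source()].
#' @param extent domain extent (mm, 3-vector).
#' @return the source with a concrete `axis_origin`.
#' @export
resolve_fiber <- function(source, extent) {
  stopifnot(inherits(source, "fiber_source"))
  if (is.null(source$axis_origin)) {
    centre <- extent / 2
    source$axis_origin <- centre - source$axis_direction * source$diffuser_length / 2
  }
  source
}

#' Diffuser segment end points
#'
#' @param source a [fiber_source()] with a resolved `axis_origin`.
#' @return a 2 x 3 matrix with the segment start and end coordinates (mm).
#' @export
fiber_endpoints <- function(source) {
  stopifnot(inherits(source, "fiber_source"))
  if (is.null(source$axis_origin)) {
    stop_validation(
      "fiber axis_origin is unresolved; build a grid (or sim_config) first or set it explicitly.")
  }
  rbind(
    start = source$axis_origin,
    end = source$axis_origin + source$axis_direction * source$diffuser_length
  )
}
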