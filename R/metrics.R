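## Iso-level lesion volumetrics on regular grids.
##
## Two estimators are reported:
##  * raw: finite-volume node counting — the sum of node weights where the
##    field meets the level (ties count as inside);
##  * corrected (default): cell-based with trilinear fractional occupancy —
##    cells whose eight corners all reach the level contribute h^3, cells
##    entirely below contribute 0, and interface cells are subsampled on a
##    4 x 4 x 4 midpoint lattice with trilinear interpolation.
## Both are monotone non-increasing in the level.

trilinear_offsets <- function(m = 4L) {
  u <- (2 * seq_len(m) - 1) / (2 * m)
  as.matrix(expand.grid(u = u, v = u, w = u))
}

## fraction of each interface cell above `level`, given the 8 corner values
## (columns c000..c111, rows = cells)
cell_fraction_above <- function(corners, level, m = 4L) {
  offs <- trilinear_offsets(m)
  frac <- numeric(nrow(corners))
  for (r in seq_len(nrow(offs))) {
    u <- offs[r, 1]; v <- offs[r, 2]; w <- offs[r, 3]
    val <-
      corners[, 1] * (1 - u) * (1 - v) * (1 - w) +
      corners[, 2] * u       * (1 - v) * (1 - w) +
      corners[, 3] * (1 - u) * v       * (1 - w) +
      corners[, 4] * u       * v       * (1 - w) +
      corners[, 5] * (1 - u) * (1 - v) * w +
      corners[, 6] * u       * (1 - v) * w +
      corners[, 7] * (1 - u) * v       * w +
      corners[, 8] * u       * v       * w
    frac <- frac + (val >= level)
  }
  frac / nrow(offs)
}

isolevel_volume_mm3 <- function(values, grid, level, correct_interface = TRUE) {
  s <- grid$shape
  h <- grid$spacing
  if (!correct_interface) {
    return(sum(node_weights(grid)[values >= level]))
  }
  i1 <- seq_len(s[1] - 1L); i2 <- i1 + 1L
  j1 <- seq_len(s[2] - 1L); j2 <- j1 + 1L
  k1 <- seq_len(s[3] - 1L); k2 <- k1 + 1L
  c000 <- values[i1, j1, k1, drop = FALSE]
  c100 <- values[i2, j1, k1, drop = FALSE]
  c010 <- values[i1, j2, k1, drop = FALSE]
  c110 <- values[i2, j2, k1, drop = FALSE]
  c001 <- values[i1, j1, k2, drop = FALSE]
  c101 <- values[i2, j1, k2, drop = FALSE]
  c011 <- values[i1, j2, k2, drop = FALSE]
  c111 <- values[i2, j2, k2, drop = FALSE]
  cmin <- pmin(c000, c100, c010, c110, c001, c101, c011, c111)
  cmax <- pmax(c000, c100, c010, c110, c001, c101, c011, c111)
  full <- cmin >= level
  mixed <- which(!full & cmax >= level)
  vol <- sum(full) * h^3
  if (length(mixed)) {
    corners <- cbind(c000[mixed], c100[mixed], c010[mixed], c110[mixed],
                     c001[mixed], c101[mixed], c011[mixed], c111[mixed])
    vol <- vol + sum(cell_fraction_above(corners, level)) * h^3
  }
  vol
}

#' Volume enclosed by an iso-level surface
#'
#' Volume of the super-level region `{field >= level}` in cubic centimetres.
#' For temperature fields the level is given in degrees Celsius (the
#' package's user-facing temperature unit); for dimensionless fields it is
#' used as is. Ties (`value == level`) count as inside.
#'
#' @param field a `scalar_field`.
#' @param level iso level: degrees Celsius for kelvin fields, raw value
#'   otherwise.
#' @param correct_interface apply the trilinear fractional-occupancy
#'   correction on interface cells (default). When `FALSE`, plain
#'   finite-volume node counting is used.
#' @return volume in cc (= cm^3).
#' @examples
#' fx <- generate_fixture("radial_linear")
#' isolevel_volume(fx$field, 43)        # ~ 4/3 pi 8^3 mm^3 = 2.145 cc
#' fx$true_isolevel_volume_cc(43)
#' @export
isolevel_volume <- function(field, level, correct_interface = TRUE) {
  stopifnot(inherits(field, "scalar_field"))
  check_number(level, "level")
  if (n_nodes(field$grid) == 0L) {
    stop_validation("cannot compute a volume on an empty grid.")
  }
  lev <- if (field$unit == "kelvin") celsius_to_kelvin(level) else level
  isolevel_volume_mm3(field$values, field$grid, lev, correct_interface) / 1000
}

#' Volume enclosed by an iso-damage surface
#'
#' Volume of the region whose damage integral meets `omega_level`
#' (default 1, the coagulative-necrosis border).
#'
#' @param damage a [damage_field()] or a dimensionless `scalar_field` of
#'   damage-integral values.
#' @param omega_level damage-integral iso level. Default 1.
#' @param correct_interface see [isolevel_volume()].
#' @return volume in cc.
#' @export
isodamage_volume <- function(damage, omega_level = 1, correct_interface = TRUE) {
  if (inherits(damage, "damage_field")) damage <- damage$omega
  stopifnot(inherits(damage, "scalar_field"))
  check_number(omega_level, "omega_level", lower = 0)
  isolevel_volume(damage, omega_level, correct_interface)
}

#' Principal bounding axes of a lesion
#'
#' Extents of the super-level region along the fiber axis and the two
#' perpendicular directions, measured as the node-coordinate span plus one
#' node spacing (so an isolated node has extent `spacing`, not zero). The
#' lesion is flagged prolate when the axial length strictly exceeds both
#' perpendicular lengths — the expected shape around a linear diffuser.
#'
#' @param field a `scalar_field`.
#' @param level iso level (degrees C for kelvin fields).
#' @param axis unit 3-vector of the fiber axis, or a [fiber_source()] whose
#'   axis is used. Default x.
#' @return a tibble with one row: `axial_mm`, `perp1_mm`, `perp2_mm`,
#'   `prolate`, `empty`, `n_nodes`. An empty super-level set yields a row
#'   with `empty = TRUE` and `NA` lengths (not an error).
#' @export
lesion_axes <- function(field, level, axis = c(1, 0, 0)) {
  stopifnot(inherits(field, "scalar_field"))
  if (inherits(axis, "fiber_source")) axis <- axis$axis_direction
  axis <- check_vector3(axis, "axis")
  axis <- axis / sqrt(sum(axis^2))
  lev <- if (field$unit == "kelvin") celsius_to_kelvin(level) else level
  inside <- as.vector(field$values) >= lev
  if (!any(inside)) {
    return(tibble(axial_mm = NA_real_, perp1_mm = NA_real_,
                  perp2_mm = NA_real_, prolate = NA, empty = TRUE,
                  n_nodes = 0L))
  }
  ## orthonormal frame around the fiber axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * axis) * axis
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(axis[2] * e2[3] - axis[3] * e2[2],
          axis[3] * e2[1] - axis[1] * e2[3],
          axis[1] * e2[2] - axis[2] * e2[1])
  pts <- node_coordinates(field$grid)[inside, , drop = FALSE]
  span <- function(e) diff(range(pts %*% e)) + field$grid$spacing
  lens <- c(span(axis), span(e2), span(e3))
  tibble(
    axial_mm = lens[1], perp1_mm = lens[2], perp2_mm = lens[3],
    prolate = lens[1] > lens[2] & lens[1] > lens[3],
    empty = FALSE, n_nodes = sum(inside)
  )
}

#' Summarise a lesion at several iso levels
#'
#' @param field a `scalar_field` (temperature in kelvin, or damage).
#' @param levels iso levels (degrees C for kelvin fields). Default
#'   `c(43, 45, 50)`.
#' @param axis fiber axis for the shape description (see [lesion_axes()]).
#' @return a tibble with one row per level: corrected and raw volumes (cc
#'   and mm^3) and the lesion axes.
#' @export
lesion_summary <- function(field, levels = c(43, 45, 50), axis = c(1, 0, 0)) {
  stopifnot(inherits(field, "scalar_field"))
  rows <- lapply(levels, function(lv) {
    ax <- lesion_axes(field, lv, axis)
    tibble(
      level = lv,
      volume_cc = isolevel_volume(field, lv),
      volume_raw_cc = isolevel_volume(field, lv, correct_interface = FALSE),
      axial_mm = ax$axial_mm, perp1_mm = ax$perp1_mm, perp2_mm = ax$perp2_mm,
      prolate = ax$prolate, empty = ax$empty
    )
  })
  out <- dplyr::bind_rows(rows)
  out$volume_mm3 <- out$volume_cc * 1000
  class(out) <- c("litt_lesion_summary", class(out))
  out
}

## ---- cohort statistics ------------------------------------------------------

#' Mean and sample standard deviation of cohort lesion volumes
#'
#' @param volumes numeric vector of per-subject volumes (cc), length >= 2.
#' @return a tibble with columns `n`, `mean_cc`, `sd_cc` (sample, n-1,
#'   standard deviation).
#' @examples
#' cohort_stats(rat_necrosis_volumes()$mri_cc)
#' @export
cohort_stats <- function(volumes) {
  if (!is.numeric(volumes) || length(volumes) < 2L) {
    stop_validation("`volumes` must be a numeric vector of length >= 2.")
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop_validation("all volumes must be finite and positive.")
  }
  tibble(n = length(volumes), mean_cc = mean(volumes), sd_cc = sd(volumes))
}

#' Pearson correlation of paired volume measurements
#'
#' @param a,b equal-length numeric vectors (length >= 3) of paired volumes,
#'   each with nonzero variance.
#' @return the Pearson product-moment correlation coefficient.
#' @examples
#' with(rat_necrosis_volumes(), paired_correlation(mri_cc, histology_cc))
#' @export
paired_correlation <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b) ||
      length(a) < 3L) {
    stop_validation("`a` and `b` must be equal-length numeric vectors, length >= 3.")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop_validation("correlation is undefined for constant input.")
  }
  cor(a, b)
}

#' Energy-to-volume dosimetry ratio
#'
#' @param energy_J delivered energy (J).
#' @param volume_cc ablated volume (cc), must be positive.
#' @return ratio in J/cm^3.
#' @examples
#' energy_volume_ratio(3260, 4.5)     # 724.4
#' energy_volume_ratio(5 * 75, 1)     # 375: the reference protocol over 1 cc
#' @export
energy_volume_ratio <- function(energy_J, volume_cc) {
  check_number(energy_J, "energy_J", lower = 0)
  if (!is.numeric(volume_cc) || length(volume_cc) != 1L ||
      !is.finite(volume_cc) || volume_cc <= 0) {
    stop_validation("`volume_cc` must be a single positive number.")
  }
  energy_J / volume_cc
}

#' In vivo necrosis-volume validation cohort
#'
#' Per-subject coagulative-necrosis volumes for the ten-rat validation
#' cohort of the reference ablation protocol (5 W, 75 s), measured on 48 h
#' post-treatment MR images and on histology. Shipped with the package as a
#' plain CSV fixture.
#'
#' @return a tibble with columns `rat`, `mri_cc`, `histology_cc`.
#' @export
rat_necrosis_volumes <- function() {
  path <- system.file("extdata", "rat_necrosis_volumes.csv",
                      package = "littsim", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Published benchmark isotherm volumes
#'
#' The simulated iso-temperature lesion volumes reported by the in vivo
#' validation study of the reference protocol, used by the `validate`
#' pipeline for its discrepancy analysis.
#'
#' @return a tibble with columns `level_C`, `volume_cc`.
#' @export
benchmark_isotherm_volumes <- function() {
  path <- system.file("extdata", "benchmark_isotherm_volumes.csv",
                      package = "littsim", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
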