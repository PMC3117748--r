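#' Thermal and perfusion properties of the target tissue
#'
#' Bundles the tissue constants of the Pennes bioheat equation. Defaults are
#' literature values for Dunning rat prostate adenocarcinoma at 980 nm, in the
#' package's mm-g-s-J-K unit system, so they can be used verbatim without
#' conversion.
#'
#' The perfusion sink in the bioheat equation is
#' `w_vol * rho_b * c_b * (T_b - T)`, where the volumetric perfusion rate
#' `w_vol` (1/s) is derived from the mass-specific blood flow rate `perfusion`
#' (ml/g/min) as `perfusion * density * 1000 / 60`; see
#' [volumetric_perfusion_rate()].
#'
#' @param density tissue density `rho` (g/mm^3). Default 0.999e-3.
#' @param specific_heat specific heat capacity `c` (J/g/K). Default 4.20.
#' @param conductivity thermal conductivity `k` (W/mm/K). Default 5.52e-4.
#'   May be set to zero to disable conduction in verification runs.
#' @param perfusion blood flow rate `w_b` (ml/g/min). Default 0.10.
#' @param blood_temperature_C arterial blood temperature (degrees C). Default 37.
#' @param metabolic_heat volumetric metabolic heat source (W/mm^3). Default 0;
#'   metabolic heating is negligible on the 75 s ablation time scale.
#' @param blood_density,blood_specific_heat blood properties; default equal to
#'   the tissue values.
#' @return an object of class `tissue_properties`.
#' @examples
#' tissue_properties()
#' # thermal diffusivity alpha = k / (rho c), about 0.1316 mm^2/s:
#' with(tissue_properties(), conductivity / (density * specific_heat))
#' @export
tissue_properties <- function(density = 0.999e-3,
                              specific_heat = 4.20,
                              conductivity = 5.52e-4,
                              perfusion = 0.10,
                              blood_temperature_C = 37,
                              metabolic_heat = 0,
                              blood_density = density,
                              blood_specific_heat = specific_heat) {
  check_number(density, "density", lower = 0, strict_lower = TRUE)
  check_number(specific_heat, "specific_heat", lower = 0, strict_lower = TRUE)
  check_number(conductivity, "conductivity", lower = 0)
  check_number(perfusion, "perfusion", lower = 0)
  check_number(blood_temperature_C, "blood_temperature_C", lower = -273.15,
               strict_lower = TRUE)
  check_number(metabolic_heat, "metabolic_heat", lower = 0)
  check_number(blood_density, "blood_density", lower = 0, strict_lower = TRUE)
  check_number(blood_specific_heat, "blood_specific_heat", lower = 0,
               strict_lower = TRUE)
  structure(
    list(
      density = density,
      specific_heat = specific_heat,
      conductivity = conductivity,
      perfusion = perfusion,
      blood_temperature = celsius_to_kelvin(blood_temperature_C),
      metabolic_heat = metabolic_heat,
      blood_density = blood_density,
      blood_specific_heat = blood_specific_heat
    ),
    class = "tissue_properties"
  )
}

#' Volumetric perfusion rate
#'
#' Converts the mass-specific blood flow rate `w_b` (ml blood per g tissue per
#' minute) into the volumetric rate (1/s) that multiplies the perfusion sink
#' term: `w_b * rho * 1000 / 60`. With the default tissue this is
#' 1.665e-3 1/s.
#'
#' @param tissue a [tissue_properties()] object.
#' @return volumetric perfusion rate (1/s).
#' @examples
#' volumetric_perfusion_rate(tissue_properties())
#' @export
volumetric_perfusion_rate <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_properties"))
  tissue$perfusion * tissue$density * 1000 / 60
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat("<tissue_properties>  (mm-g-s-J-K units)\n")
  cat(sprintf("  density        %.4g g/mm^3\n", x$density))
  cat(sprintf("  specific heat  %.4g J/g/K\n", x$specific_heat))
  cat(sprintf("  conductivity   %.4g W/mm/K\n", x$conductivity))
  cat(sprintf("  perfusion      %.4g ml/g/min (volumetric %.4g 1/s)\n",
              x$perfusion, volumetric_perfusion_rate(x)))
  cat(sprintf("  blood T        %.2f C\n", kelvin_to_celsius(x$blood_temperature)))
  cat(sprintf("  metabolic heat %.4g W/mm^3\n", x$metabolic_heat))
  invisible(x)
}

#' Arrhenius damage kinetics
#'
#' Rate parameters of the first-order Arrhenius model of thermal tissue
#' damage. Defaults are the published kinetic constants for Dunning rat
#' prostate tissue. The gas constant defaults to the CODATA universal value;
#' it is exposed as a parameter because some published parameter tables print
#' non-standard values for it.
#'
#' @param frequency_factor `A_f` (1/s). Default 3.8e14.
#' @param activation_energy `E_a` (J/mol). Default 1.084e5.
#' @param gas_constant `R` (J/mol/K). Default 8.314462618.
#' @return an object of class `kinetic_parameters`.
#' @seealso [accumulate_damage()], [threshold_temperature()],
#'   [calibrate_frequency_factor()]
#' @examples
#' kinetic_parameters()
#' @export
kinetic_parameters <- function(frequency_factor = 3.8e14,
                               activation_energy = 1.084e5,
                               gas_constant = 8.314462618) {
  check_number(frequency_factor, "frequency_factor", lower = 0, strict_lower = TRUE)
  check_number(activation_energy, "activation_energy", lower = 0, strict_lower = TRUE)
  check_number(gas_constant, "gas_constant", lower = 0, strict_lower = TRUE)
  structure(
    list(
      frequency_factor = frequency_factor,
      activation_energy = activation_energy,
      gas_constant = gas_constant
    ),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("<kinetic_parameters>\n")
  cat(sprintf("  A_f %.4g 1/s,  E_a %.4g J/mol,  R %.6g J/mol/K\n",
              x$frequency_factor, x$activation_energy, x$gas_constant))
  invisible(x)
}
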