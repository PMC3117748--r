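# littsim

Simulation of interstitial **focal laser ablation** (laser interstitial
thermal therapy, LITT) of soft tissue around a cylindrical diffusing fiber,
with thermal-damage dosimetry and lesion volumetrics.

The package is aimed at thermal-therapy modellers who want a small, fully
tested reference implementation of the classic LITT simulation chain:

1. **Bioheat transfer.** The Pennes equation on a homogeneous tissue block,

   ρ C ∂T/∂t = k ∇²T + w·ρ_b·C_b (T_b − T) + Q_abs + Q_met,

   with tissue density ρ, specific heat C, conductivity k, volumetric blood
   perfusion w (derived from the mass-specific flow rate in ml·g⁻¹·min⁻¹),
   arterial temperature T_b, and the laser deposition Q_abs. It is solved
   implicitly (backward Euler, Crank–Nicolson optional) on a regular
   node-centred grid with zero-flux outer faces, using restarted GMRES with
   Jacobi preconditioning (direct sparse factorisation on small grids).

2. **Arrhenius thermal damage.** The damage integral
   Ω(τ) = A_f ∫₀^τ exp(−E_a / (R·T(t))) dt accumulated over the temperature
   history (streamed during the simulation, so full histories need not be
   stored). The destroyed-concentration fraction is 1 − e^(−Ω); Ω = 1
   (63.2 %) marks the coagulative-necrosis border. CEM43 thermal dose is
   also provided.

3. **Lesion metrics.** Iso-temperature / iso-damage volumes on the voxel
   grid (with a trilinear interface correction), lesion bounding axes and a
   prolate-shape flag, plus the cohort statistics (mean, sample SD, Pearson
   correlation) for the packaged ten-subject in vivo necrosis-volume
   dataset, and energy-per-volume dosimetry ratios.

Default parameters encode the reference preclinical protocol: a
70 × 70 × 20 mm tissue block, rat-prostate thermal/kinetic constants, a
10 mm diffuser delivering 5 W for 75 s from a 37 °C start.

## Worked example

```r
library(littsim)

cfg <- sim_config(grid_spacing = 1)   # reference protocol, 1 mm grid
sim <- simulate_fla(cfg)
glance(sim)
#>   n_nodes spacing_mm mode            duration_s peak_C energy_deposited_J necrosis_volume_cc
#> 1  105861          1 uniform_capsule         75   94.5                375              0.276

lesion_summary(sim$final, axis = cfg$source)
#>   level volume_cc volume_raw_cc axial_mm perp1_mm perp2_mm prolate
#> 1    43      3.32          3.26       23       15       15 TRUE
#> 2    45      2.73          2.67       23       15       15 TRUE
#> 3    50      1.89          1.89       21       13       13 TRUE
```

The peak tissue temperature (94.5 °C) sits next to the 91 ± 1 °C measured
at the fiber tip in the in vivo protocol, the lesion is prolate with its
long axis along the diffuser, and the iso-volumes shrink with the level, as
they must. `tidy(sim)` returns the per-step solver log and
`autoplot(sim)` the mid-plane temperature map.

Damage kinetics are exposed directly:

```r
kelvin_to_celsius(threshold_temperature(75, kinetic_parameters()))
#> 70.95  # constant hold reaching omega = 1 in 75 s
damage_fraction(1)
#> 0.632
```

and the packaged validation cohort:

```r
cohort_stats(rat_necrosis_volumes()$mri_cc)
#>    n mean_cc  sd_cc
#> 1 10   0.980 0.0526
with(rat_necrosis_volumes(), paired_correlation(mri_cc, histology_cc))
#> 0.877
```

A command-line driver (`inst/cli/littsim.R`) wraps the same pipeline:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","littsim.R",package="littsim"))')" \
    validate --grid-spacing 1 --out run1
```

writes `cohort_stats.csv`, `isotherm_volumes.csv`, a plain-text validation
report with a discrepancy analysis, and a reproducible `manifest.yaml`.

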