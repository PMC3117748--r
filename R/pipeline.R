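#' Run a named pipeline stage and write a reproducible manifest
#'
#' Drives the package end to end from a configuration, writing all stage
#' outputs plus a `manifest.yaml` that echoes the fully-expanded
#' configuration (sufficient to reproduce the run), the package version, the
#' stage log, and an inventory of every output file with its MD5 checksum.
#' Identical configuration and seed give bit-identical outputs and an
#' identical manifest up to timestamps.
#'
#' Commands:
#' * `"simulate"` — run the thermal simulation; writes the final temperature
#'   field, the streamed damage-integral field, and the per-step peak log.
#' * `"damage"` — as `simulate`, then writes the damage summary
#'   (necrosis-border volume at the damage-integral levels).
#' * `"metrics"` — iso-level lesion summary of a field (either
#'   `field_path`, a previously exported field, or a fresh simulation).
#' * `"validate"` — the full validation analysis: cohort statistics and
#'   paired correlation of the packaged in vivo necrosis volumes, plus the
#'   simulated isotherm volumes at 43/45/50 C compared against the published
#'   benchmark volumes, with a discrepancy analysis.
#'
#' @param command one of `"simulate"`, `"damage"`, `"metrics"`,
#'   `"validate"`.
#' @param config a [sim_config()], a path to a YAML configuration file, or
#'   `NULL` for the package defaults.
#' @param out_dir output directory (created if needed).
#' @param grid_spacing,mode,cooldown_s optional overrides of the
#'   configuration's grid spacing, source mode, and cooldown duration.
#' @param levels iso-temperature levels (C) for metrics/validate.
#' @param omega_levels damage-integral levels for the damage summary.
#' @param field_path optional path of an exported field for `"metrics"`.
#' @param field_format export format for 3-d fields. Default `"vtk"`.
#' @param seed integer seed (the pipeline itself is deterministic; the seed
#'   is recorded and applied for reproducibility of any downstream
#'   stochastic additions).
#' @param verbose forward per-step logging from the solver.
#' @return the manifest (class `litt_manifest`), invisibly. On a stage
#'   error the manifest (with the failure recorded) is written before the
#'   error is re-signalled.
#' @export
run_pipeline <- function(command = c("simulate", "damage", "metrics", "validate"),
                         config = NULL,
                         out_dir = "littsim-out",
                         grid_spacing = NULL,
                         mode = NULL,
                         cooldown_s = NULL,
                         levels = c(43, 45, 50),
                         omega_levels = c(0.5, 1),
                         field_path = NULL,
                         field_format = "vtk",
                         seed = 1L,
                         verbose = FALSE) {
  command <- match.arg(command)
  config <- normalise_config(config, grid_spacing, mode, cooldown_s)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))

  log_lines <- character(0)
  outputs <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
    invisible(line)
  }
  emit <- function(rel) {
    outputs <<- c(outputs, rel)
    file.path(out_dir, rel)
  }

  started <- Sys.time()
  status <- "ok"
  err_msg <- NULL

  result <- tryCatch({
    switch(command,
      simulate = stage_simulate(config, note, emit, field_format, verbose),
      damage = stage_damage(config, note, emit, field_format, omega_levels, verbose),
      metrics = stage_metrics(config, note, emit, levels, field_path, verbose),
      validate = stage_validate(config, note, emit, levels, verbose)
    )
  }, error = function(e) {
    status <<- "error"
    err_msg <<- conditionMessage(e)
    note("stage failed: %s", err_msg)
    e
  })

  manifest <- list(
    command = command,
    package = "littsim",
    version = as.character(packageVersion("littsim")),
    seed = as.integer(seed),
    config = config_as_list(config),
    status = status,
    error = err_msg,
    log = log_lines,
    outputs = file_inventory(out_dir, outputs),
    started = format(started, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"),
                   precision = 15)
  if (status == "error") stop(result)
  invisible(structure(manifest, class = "litt_manifest"))
}

normalise_config <- function(config, grid_spacing, mode, cooldown_s) {
  if (is.null(config)) {
    config <- sim_config()
  } else if (is.character(config)) {
    config <- load_config(config)
  }
  stopifnot(inherits(config, "sim_config"))
  if (is.null(grid_spacing) && is.null(mode) && is.null(cooldown_s)) {
    return(config)
  }
  lst <- config_as_list(config)
  if (!is.null(grid_spacing)) lst$grid$spacing <- grid_spacing
  if (!is.null(mode)) lst$source$mode <- mode
  if (!is.null(cooldown_s)) lst$simulation$cooldown_duration_s <- cooldown_s
  ## a respaced grid re-centres an automatically placed fiber identically
  config_from_list(lst)
}

file_inventory <- function(out_dir, rel_paths) {
  rel_paths <- sort(unique(rel_paths))
  lapply(rel_paths, function(rel) {
    p <- file.path(out_dir, rel)
    list(path = rel,
         bytes = as.integer(file.size(p)),
         md5 = unname(tools::md5sum(p)))
  })
}

write_tibble_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

stage_simulate <- function(config, note, emit, field_format, verbose,
                           return_sim = FALSE) {
  note("simulate: %s nodes, %g s heating + %g s cooldown, mode %s",
       format(n_nodes(config$grid), big.mark = ","), config$duration,
       config$cooldown_duration, config$source$mode)
  sim <- simulate_fla(config, verbose = verbose)
  note("peak temperature %.2f C; deposited energy %.4g J",
       max(sim$step_log$peak_C), sim$energy_deposited_J)
  ext <- switch(field_format, vtk = "vtk", nifti = "nii", csv = "csv")
  export_field(sim$final, emit(paste0("temperature_final.", ext)), field_format)
  export_field(sim$damage$omega, emit(paste0("damage_omega.", ext)), field_format)
  write_tibble_csv(sim$step_log, emit("step_log.csv"))
  sim
}

stage_damage <- function(config, note, emit, field_format, omega_levels, verbose) {
  sim <- stage_simulate(config, note, emit, field_format, verbose)
  rows <- lapply(omega_levels, function(lv) {
    tibble(omega_level = lv,
           damage_fraction = damage_fraction(lv),
           volume_cc = isodamage_volume(sim$damage, lv))
  })
  summary <- dplyr::bind_rows(rows)
  for (i in seq_len(nrow(summary))) {
    note("damage: volume(omega >= %g) = %.3f cc (fraction %.3f)",
         summary$omega_level[i], summary$volume_cc[i], summary$damage_fraction[i])
  }
  write_tibble_csv(summary, emit("damage_summary.csv"))
  summary
}

stage_metrics <- function(config, note, emit, levels, field_path, verbose) {
  field <- if (!is.null(field_path)) {
    note("metrics: reading field from %s", field_path)
    read_field(field_path)
  } else {
    note("metrics: no field supplied, running the configured simulation")
    simulate_fla(config, accumulate_damage = FALSE, verbose = verbose)$final
  }
  summary <- lesion_summary(field, levels, axis = config$source)
  for (i in seq_len(nrow(summary))) {
    note("metrics: V(%g C) = %.3f cc", summary$level[i], summary$volume_cc[i])
  }
  write_tibble_csv(summary, emit("lesion_summary.csv"))
  summary
}

stage_validate <- function(config, note, emit, levels, verbose) {
  cohort <- rat_necrosis_volumes()
  stats <- dplyr::bind_rows(
    dplyr::mutate(cohort_stats(cohort$mri_cc), modality = "mri", .before = 1),
    dplyr::mutate(cohort_stats(cohort$histology_cc), modality = "histology",
                  .before = 1)
  )
  r <- paired_correlation(cohort$mri_cc, cohort$histology_cc)
  note("cohort: MRI mean %.3f +/- %.3f cc; histology mean %.3f +/- %.3f cc; Pearson r %.3f",
       stats$mean_cc[1], stats$sd_cc[1], stats$mean_cc[2], stats$sd_cc[2], r)
  write_tibble_csv(stats, emit("cohort_stats.csv"))

  sim <- simulate_fla(config, accumulate_damage = TRUE, verbose = verbose)
  summary <- lesion_summary(sim$final, levels, axis = config$source)
  bench <- benchmark_isotherm_volumes()
  names(bench)[names(bench) == "volume_cc"] <- "benchmark_cc"
  comp <- dplyr::left_join(summary, bench, by = c(level = "level_C"))
  names(comp)[names(comp) == "volume_cc"] <- "simulated_cc"
  comp$pct_diff <- 100 * (comp$simulated_cc - comp$benchmark_cc) / comp$benchmark_cc
  keep <- c("level", "simulated_cc", "benchmark_cc", "pct_diff",
            "axial_mm", "perp1_mm", "perp2_mm", "prolate")
  comp <- comp[keep]
  write_tibble_csv(comp, emit("isotherm_volumes.csv"))
  omega1_cc <- isodamage_volume(sim$damage, 1)
  report <- validation_report_text(config, sim, comp, stats, r, omega1_cc)
  writeLines(report, emit("validation_report.txt"))
  note("validate: report written (%d lines)", length(report))
  list(cohort = stats, pearson_r = r, isotherms = comp,
       omega1_volume_cc = omega1_cc)
}

validation_report_text <- function(config, sim, comp, stats, r, omega1_cc) {
  peak <- max(sim$step_log$peak_C)
  dep <- sim$energy_deposited_J
  c(
    "littsim validation report",
    "=========================",
    "",
    sprintf("Configuration: %s mode, %.3g W for %g s, %g mm grid, dt %g s.",
            config$source$mode, config$source$power, config$duration,
            config$grid$spacing, config$dt),
    "",
    "In vivo cohort (packaged ten-subject dataset):",
    sprintf("  MRI (48 h):  mean %.3f cc, sample SD %.3f cc (n = %d)",
            stats$mean_cc[1], stats$sd_cc[1], stats$n[1]),
    sprintf("  histology:   mean %.3f cc, sample SD %.3f cc (n = %d)",
            stats$mean_cc[2], stats$sd_cc[2], stats$n[2]),
    sprintf("  Pearson correlation MRI vs histology: r = %.3f", r),
    "",
    "Simulated isotherm volumes vs published benchmark:",
    sprintf("  V(%g C) = %.3f cc  (benchmark %.2f cc, %+.0f%%)",
            comp$level, comp$simulated_cc, comp$benchmark_cc, comp$pct_diff),
    sprintf("  necrosis-border volume (damage integral >= 1): %.3f cc", omega1_cc),
    sprintf("  peak tissue temperature: %.2f C (measured fiber-wall value: 91 +/- 1 C)",
            peak),
    "",
    "Discrepancy analysis:",
    sprintf("  The simulation deposits the full nominal source energy (%.0f J) in", dep),
    "  tissue. With the configured heat capacity, that energy necessarily",
    sprintf("  raises roughly %.1f cc above the 43 C level (profile-dependent;",
            comp$simulated_cc[comp$level == min(comp$level)][1]),
    sprintf("  the adiabatic upper bound is %.1f cc), whereas the benchmark",
            dep / (config$tissue$density * config$tissue$specific_heat * 1000 *
                     (43 - kelvin_to_celsius(config$initial_temperature)))),
    "  volumes are consistent with only ~100-150 J reaching tissue. The",
    "  spatial deposition profile of the real diffusing applicator (and of",
    "  the original finite-element setup it emulates) is not recoverable",
    "  from the published power and peak-temperature figures alone; the",
    "  peak temperature, by contrast, agrees with the measured fiber-wall",
    "  value, and the lesion keeps the expected prolate shape with its long",
    "  axis along the diffuser. Isotherm ordering V(43) > V(45) > V(50)",
    "  holds by construction of the temperature field.",
    ""
  )
}

#' @export
print.litt_manifest <- function(x, ...) {
  cat(sprintf("<litt_manifest> %s (%s), status %s, %d output file(s)\n",
              x$command, x$version, x$status, length(x$outputs)))
  invisible(x)
}
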