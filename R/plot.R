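#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   scale_fill_viridis_c coord_equal labs theme_minimal
#' @export
ggplot2::autoplot

## Extract an axis-aligned slice of a field as a long tibble.
field_slice <- function(field, slice_axis = "z", slice_mm = NULL) {
  ax_idx <- match(slice_axis, c("x", "y", "z"))
  if (is.na(ax_idx)) stop_validation("`slice_axis` must be one of x, y, z.")
  grid <- field$grid
  slice_mm <- slice_mm %||% (grid$extent[ax_idx] / 2)
  i <- round(slice_mm / grid$spacing) + 1L
  i <- min(max(i, 1L), grid$shape[ax_idx])
  vals <- switch(ax_idx,
                 field$values[i, , ],
                 field$values[, i, ],
                 field$values[, , i])
  other <- setdiff(1:3, ax_idx)
  ax <- grid_axes(grid)
  tibble(
    h_mm = rep(ax[[other[1]]], times = grid$shape[other[2]]),
    v_mm = rep(ax[[other[2]]], each = grid$shape[other[1]]),
    value = as.vector(vals),
    h_lab = c("x", "y", "z")[other[1]],
    v_lab = c("x", "y", "z")[other[2]]
  )
}

#' Plot a planar slice of a scalar field
#'
#' @param object a `scalar_field`.
#' @param slice_axis axis normal to the slice (`"x"`, `"y"`, `"z"`).
#' @param slice_mm slice position (mm); defaults to the domain mid-plane.
#' @param ... unused.
#' @return a ggplot object (temperatures are shown in degrees Celsius).
#' @method autoplot scalar_field
#' @export
autoplot.scalar_field <- function(object, slice_axis = "z", slice_mm = NULL,
                                  ...) {
  df <- field_slice(object, slice_axis, slice_mm)
  lab <- object$unit
  if (object$unit == "kelvin") {
    df$value <- kelvin_to_celsius(df$value)
    lab <- "temperature (C)"
  }
  ggplot(df, aes(x = .data$h_mm, y = .data$v_mm, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(option = "inferno", name = lab) +
    coord_equal() +
    labs(x = paste0(df$h_lab[1], " (mm)"), y = paste0(df$v_lab[1], " (mm)")) +
    theme_minimal()
}

#' Plot a simulation: final mid-plane temperature map
#'
#' @param object an `fla_simulation`.
#' @param ... passed to `autoplot.scalar_field()`.
#' @return a ggplot object.
#' @method autoplot fla_simulation
#' @export
autoplot.fla_simulation <- function(object, ...) {
  autoplot(object$final, ...) +
    labs(title = sprintf("temperature at t = %g s (%s, %.3g W)",
                         object$config$duration + object$config$cooldown_duration,
                         object$source_term$mode, object$source_term$total_power))
}

#' Plot the per-step peak-temperature trace of a simulation
#'
#' @param sim an `fla_simulation`.
#' @return a ggplot object.
#' @export
plot_step_log <- function(sim) {
  stopifnot(inherits(sim, "fla_simulation"))
  ggplot(sim$step_log, aes(x = .data$time_s, y = .data$peak_C,
                           colour = .data$phase)) +
    geom_line() +
    labs(x = "time (s)", y = "peak temperature (C)") +
    theme_minimal()
}

#' Plot a lesion summary as volumes per iso level
#'
#' @param object a tibble from [lesion_summary()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot litt_lesion_summary
#' @export
autoplot.litt_lesion_summary <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$level), y = .data$volume_cc)) +
    geom_col(fill = "firebrick") +
    labs(x = "iso level (C)", y = "volume (cc)") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
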