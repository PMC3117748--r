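## Implicit finite-difference solver for the Pennes bioheat equation
##
##   rho c dT/dt = k lap(T) + w_vol rho_b c_b (T_b - T) + Q_abs + Q_met
##
## on a regular node-centred grid with zero-flux outer faces. The spatial
## operator uses the 7-point Laplacian; boundary nodes carry the mirrored
## ghost-node form, which is identical to the finite-volume discretisation
## with half cells at the faces, so the scheme conserves energy exactly
## (up to the linear-solver residual) in adiabatic runs.

## Assemble the time-independent parts of the linear system.
## The loss operator  Lop = k * (-lap) + w_vol rho_b c_b * I  (clamped rows
## zeroed) is stored as a sparse matrix; a theta-scheme step solves
##   (rho c / dt) I + theta * Lop  acting on T_new =
##   (rho c / dt) T - (1-theta) * Lop T + (w_vol rho_b c_b T_b + q)
## with theta = 1 (backward Euler) or 1/2 (Crank-Nicolson).
assemble_bioheat_system <- function(grid, tissue, source_term, dt,
                                    time_integration = "backward_euler",
                                    active = TRUE) {
  s <- grid$shape
  n <- prod(s)
  h <- grid$spacing
  kh2 <- tissue$conductivity / h^2
  w_sink <- volumetric_perfusion_rate(tissue) *
    tissue$blood_density * tissue$blood_specific_heat   # W/mm^3/K
  rc_dt <- tissue$density * tissue$specific_heat / dt

  idx <- array(seq_len(n), dim = s)
  rows <- vector("list", 6)
  cols <- vector("list", 6)
  vals <- vector("list", 6)
  diag_l <- rep(w_sink, n)
  slot <- 1L
  for (ax in 1:3) {
    n_ax <- s[ax]
    coord <- slice.index(idx, ax)
    for (step in c(-1L, 1L)) {
      inside <- if (step == 1L) coord < n_ax else coord > 1L
      ## mirrored ghost: the single neighbour of a face node counts twice
      coef <- ifelse(coord == 1L | coord == n_ax, 2 * kh2, kh2)
      from <- idx[inside]
      to <- from + step * cumprod(c(1L, s))[ax]
      rows[[slot]] <- from
      cols[[slot]] <- to
      vals[[slot]] <- -coef[inside]
      diag_l <- diag_l + as.vector(coef * inside)
      slot <- slot + 1L
    }
  }
  rows <- unlist(rows); cols <- unlist(cols); vals <- unlist(vals)

  clamped <- if (active) source_term$clamped_nodes else integer(0)
  if (length(clamped)) {
    keep <- !(rows %in% clamped)
    rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]
    diag_l[clamped] <- 0
  }
  Lop <- sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n)) +
    Diagonal(n, diag_l)

  theta <- if (time_integration == "crank_nicolson") 0.5 else 1
  A <- Diagonal(n, rc_dt) + theta * Lop
  q <- if (active) as.vector(source_term$volumetric_power$values) else rep(0, n)
  const <- w_sink * tissue$blood_temperature + q + tissue$metabolic_heat
  if (length(clamped)) const[clamped] <- 0

  structure(
    list(
      A = methods::as(A, "CsparseMatrix"),
      Lop = Lop,
      diag_A = rc_dt + theta * diag_l,
      rc_dt = rc_dt,
      theta = theta,
      const = const,
      clamped = clamped,
      clamp_temperature = source_term$clamp_temperature,
      n = n,
      factor = new.env(parent = emptyenv())
    ),
    class = "bioheat_system"
  )
}

## Restarted GMRES with Jacobi (diagonal) left preconditioning.
## Convergence: preconditioned residual reduced below `tol` relative to the
## larger of the initial-guess residual and the right-hand-side norm.
gmres_solve <- function(A, b, x0, diag_A, tol, restart = 30L,
                        max_restarts = 40L) {
  minv <- 1 / diag_A
  x <- x0
  r <- minv * (b - as.numeric(A %*% x))
  beta0 <- max(sqrt(sum(r^2)), tol * sqrt(sum((minv * b)^2)), 1e-300)
  target <- tol * beta0
  total_it <- 0L
  for (outer in seq_len(max_restarts)) {
    beta <- sqrt(sum(r^2))
    if (beta <= target) {
      return(list(x = x, iterations = total_it, residual = beta / beta0))
    }
    V <- matrix(0, length(b), restart + 1L)
    H <- matrix(0, restart + 1L, restart)
    cs <- sn <- numeric(restart)
    g <- numeric(restart + 1L)
    V[, 1] <- r / beta
    g[1] <- beta
    k_used <- 0L
    for (k in seq_len(restart)) {
      w <- minv * as.numeric(A %*% V[, k])
      for (i in seq_len(k)) {        # modified Gram-Schmidt
        H[i, k] <- sum(w * V[, i])
        w <- w - H[i, k] * V[, i]
      }
      H[k + 1L, k] <- sqrt(sum(w^2))
      if (H[k + 1L, k] > 0) V[, k + 1L] <- w / H[k + 1L, k]
      for (i in seq_len(k - 1L)) {   # apply stored Givens rotations
        tmp <- cs[i] * H[i, k] + sn[i] * H[i + 1L, k]
        H[i + 1L, k] <- -sn[i] * H[i, k] + cs[i] * H[i + 1L, k]
        H[i, k] <- tmp
      }
      denom <- sqrt(H[k, k]^2 + H[k + 1L, k]^2)
      cs[k] <- H[k, k] / denom
      sn[k] <- H[k + 1L, k] / denom
      H[k, k] <- denom
      H[k + 1L, k] <- 0
      g[k + 1L] <- -sn[k] * g[k]
      g[k] <- cs[k] * g[k]
      k_used <- k
      total_it <- total_it + 1L
      if (abs(g[k + 1L]) <= target) break
    }
    y <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                   g[seq_len(k_used)])
    x <- x + V[, seq_len(k_used), drop = FALSE] %*% y
    x <- as.numeric(x)
    r <- minv * (b - as.numeric(A %*% x))
    if (sqrt(sum(r^2)) <= target) {
      return(list(x = x, iterations = total_it,
                  residual = sqrt(sum(r^2)) / beta0))
    }
  }
  stop_solver(sprintf(
    "linear solver failed to converge: relative residual %.3g after %d iterations (target %.3g).",
    sqrt(sum(r^2)) / beta0, total_it, tol))
}

solve_bioheat_step <- function(system, T_vec, tol, linear_solver = "auto") {
  rhs <- system$rc_dt * T_vec + system$const
  if (system$theta < 1) {
    rhs <- rhs - (1 - system$theta) * as.numeric(system$Lop %*% T_vec)
  }
  if (length(system$clamped)) {
    rhs[system$clamped] <- system$rc_dt * system$clamp_temperature
  }
  direct <- switch(linear_solver,
    direct = TRUE,
    iterative = FALSE,
    auto = system$n <= 25000L
  )
  if (direct) {
    if (is.null(system$factor$lu)) {
      system$factor$lu <- lu(system$A)
    }
    x <- as.numeric(solve(system$factor$lu, rhs))
    list(x = x, iterations = 0L, residual = 0)
  } else {
    gmres_solve(system$A, rhs, T_vec, system$diag_A, tol)
  }
}

#' Advance a temperature field by one implicit time step
#'
#' Performs a single implicit (backward-Euler by default) step of the Pennes
#' bioheat equation with a 7-point Laplacian, zero-flux outer faces, the
#' perfusion sink, and the given discrete source; clamped nodes (dirichlet
#' mode) are held at the wall temperature. The sparse system is solved either
#' by a cached LU factorisation (small grids) or by restarted GMRES with
#' Jacobi preconditioning to the configured relative tolerance.
#'
#' For multi-step runs use [simulate_fla()], which assembles the system once.
#'
#' @param temperature a kelvin `scalar_field` on the configuration's grid.
#' @param src a `source_term` from [assemble_source()].
#' @param config a [sim_config()].
#' @param system optional pre-assembled system (internal use).
#' @return the temperature `scalar_field` after one step of `config$dt`.
#' @export
step_temperature <- function(temperature, src, config, system = NULL) {
  stopifnot(inherits(temperature, "scalar_field"),
            inherits(src, "source_term"),
            inherits(config, "sim_config"))
  if (temperature$unit != "kelvin") {
    stop_validation("`temperature` must be a kelvin field.")
  }
  if (!identical(temperature$grid$shape, config$grid$shape)) {
    stop_validation("temperature field and configuration use different grids.")
  }
  if (is.null(system)) {
    system <- assemble_bioheat_system(config$grid, config$tissue, src,
                                      config$dt, config$time_integration)
  }
  T_vec <- as.vector(temperature$values)
  if (length(system$clamped)) T_vec[system$clamped] <- system$clamp_temperature
  sol <- solve_bioheat_step(system, T_vec, config$linear_solver_tolerance,
                            config$linear_solver)
  scalar_field(config$grid, sol$x, unit = "kelvin")
}

#' Temperature history container
#'
#' An ordered sequence of temperature fields on a shared grid, starting at
#' time 0. Produced by [simulate_fla()] (with `keep_history = TRUE`) and by
#' [generate_fixture()]; consumed by [accumulate_damage()] and [cem43()].
#'
#' @param grid a `sim_grid`.
#' @param times strictly increasing numeric vector starting at 0 (s).
#' @param fields list of kelvin value arrays (one per time).
#' @return an object of class `temperature_history`.
#' @export
temperature_history <- function(grid, times, fields) {
  stopifnot(inherits(grid, "sim_grid"))
  if (length(times) != length(fields)) {
    stop_validation("`times` and `fields` must have equal length.")
  }
  if (length(times) == 0L) {
    stop_validation("a temperature history must contain at least one frame.")
  }
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop_validation("history times must be strictly increasing and start at 0.")
  }
  for (f in fields) {
    if (length(f) != n_nodes(grid)) {
      stop_validation("every history frame must have one value per grid node.")
    }
  }
  structure(list(grid = grid, times = as.numeric(times), fields = fields),
            class = "temperature_history")
}

#' @export
print.temperature_history <- function(x, ...) {
  cat(sprintf("<temperature_history> %d frames over %g s on %s nodes\n",
              length(x$times), max(x$times),
              format(n_nodes(x$grid), big.mark = ",")))
  invisible(x)
}

#' @rdname temperature_history
#' @param history a `temperature_history`.
#' @param i frame index.
#' @export
history_frame <- function(history, i) {
  scalar_field(history$grid, history$fields[[i]], unit = "kelvin")
}

#' Simulate a focal laser ablation run
#'
#' Runs the full implicit time integration of the Pennes bioheat equation:
#' a uniform start at the configured initial temperature, `duration` seconds
#' of heating with the fiber source active, and optionally
#' `cooldown_duration` seconds with the source switched off (volumetric
#' deposition zeroed, clamps released). Arrhenius damage is accumulated in a
#' streaming fashion alongside the integration (trapezoidal rule over the
#' same time points), so full temperature histories need not be retained on
#' large grids.
#'
#' @param config a [sim_config()].
#' @param keep_history keep every `history_stride`-th temperature frame
#'   (plus the initial and final ones) as a [temperature_history()]. Off by
#'   default: a 0.5 mm reference grid holds ~8e5 nodes per frame.
#' @param history_stride keep every this-many-th frame when
#'   `keep_history = TRUE`.
#' @param accumulate_damage stream the Arrhenius damage integral (with
#'   `config$kinetics`) alongside the run.
#' @param callback optional `function(field, time_s)` invoked after every
#'   step — a streaming accessor for damage or dose accumulation on grids too
#'   large to store.
#' @param verbose print a per-step log line (time, peak temperature, solver
#'   iterations, residual).
#' @return an object of class `fla_simulation` with elements
#'   `final` (kelvin `scalar_field` at the end of the run), `damage`
#'   (a [damage_field()] or `NULL`), `history` (or `NULL`),
#'   `step_log` (tibble: step, phase, time_s, peak_C, mean_C, iterations,
#'   residual), `energy_deposited_J`, `config`, and `source_term`.
#' @examples
#' cfg <- sim_config(grid_extent = c(20, 20, 20), grid_spacing = 2,
#'                   duration_s = 5)
#' sim <- simulate_fla(cfg)
#' glance(sim)
#' @export
simulate_fla <- function(config,
                         keep_history = FALSE,
                         history_stride = 1L,
                         accumulate_damage = TRUE,
                         callback = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  n <- n_nodes(grid)
  src <- assemble_source(grid, config$source)
  sys_on <- assemble_bioheat_system(grid, config$tissue, src, config$dt,
                                    config$time_integration, active = TRUE)
  n_heat <- as.integer(round(config$duration / config$dt))
  n_cool <- as.integer(round(config$cooldown_duration / config$dt))

  T_vec <- rep(config$initial_temperature, n)

  kin <- config$kinetics
  omega <- if (accumulate_damage) rep(0, n) else NULL
  rate_prev <- if (accumulate_damage) arrhenius_rate(T_vec, kin) else NULL

  times <- 0
  frames <- list()
  kept_times <- numeric(0)
  if (keep_history) {
    frames[[1]] <- array(T_vec, dim = grid$shape)
    kept_times <- 0
  }

  log_step <- integer(0); log_phase <- character(0); log_time <- numeric(0)
  log_peak <- numeric(0); log_mean <- numeric(0)
  log_iter <- integer(0); log_res <- numeric(0)

  run_phase <- function(system, n_steps, phase, t_offset, step_offset) {
    for (k in seq_len(n_steps)) {
      sol <- solve_bioheat_step(system, T_vec, config$linear_solver_tolerance,
                                config$linear_solver)
      T_vec <<- sol$x
      t_now <- t_offset + k * config$dt
      times <<- c(times, t_now)
      if (accumulate_damage) {
        rate_now <- arrhenius_rate(T_vec, kin)
        omega <<- omega + kin$frequency_factor * config$dt / 2 *
          (rate_prev + rate_now)
        rate_prev <<- rate_now
      }
      keep_this <- keep_history &&
        ((k %% history_stride == 0L) || k == n_steps)
      if (keep_this) {
        frames[[length(frames) + 1L]] <<- array(T_vec, dim = grid$shape)
        kept_times <<- c(kept_times, t_now)
      }
      peak <- max(T_vec); mn <- mean(T_vec)
      log_step <<- c(log_step, step_offset + k)
      log_phase <<- c(log_phase, phase)
      log_time <<- c(log_time, t_now)
      log_peak <<- c(log_peak, kelvin_to_celsius(peak))
      log_mean <<- c(log_mean, kelvin_to_celsius(mn))
      log_iter <<- c(log_iter, sol$iterations)
      log_res <<- c(log_res, sol$residual)
      if (verbose) {
        message(sprintf("[%s] t = %6.1f s  peak %7.2f C  mean %6.2f C  (%d it, res %.2g)",
                        phase, t_now, kelvin_to_celsius(peak),
                        kelvin_to_celsius(mn), sol$iterations, sol$residual))
      }
      if (!is.null(callback)) {
        callback(scalar_field(grid, T_vec, unit = "kelvin"), t_now)
      }
    }
  }

  run_phase(sys_on, n_heat, "heating", 0, 0L)
  if (n_cool > 0L) {
    sys_off <- assemble_bioheat_system(grid, config$tissue, src, config$dt,
                                       config$time_integration, active = FALSE)
    run_phase(sys_off, n_cool, "cooldown", config$duration, n_heat)
  }

  history <- if (keep_history) {
    temperature_history(grid, unique(kept_times), frames[!duplicated(kept_times)])
  } else NULL

  damage <- if (accumulate_damage) {
    damage_field(scalar_field(grid, omega, unit = "dimensionless"),
                 tau = max(times), kinetics = kin)
  } else NULL

  structure(
    list(
      config = config,
      source_term = src,
      final = scalar_field(grid, T_vec, unit = "kelvin"),
      damage = damage,
      history = history,
      step_log = tibble(
        step = log_step, phase = log_phase, time_s = log_time,
        peak_C = log_peak, mean_C = log_mean,
        iterations = log_iter, residual = log_res
      ),
      energy_deposited_J = src$total_power * config$duration
    ),
    class = "fla_simulation"
  )
}

#' @export
print.fla_simulation <- function(x, ...) {
  cat("<fla_simulation>\n")
  print(x$config$grid)
  cat(sprintf("  mode %s, %g W for %g s (+%g s cooldown), peak %.2f C\n",
              x$source_term$mode, x$source_term$total_power, x$config$duration,
              x$config$cooldown_duration, max(x$step_log$peak_C)))
  if (!is.null(x$damage)) {
    cat(sprintf("  max omega %.3g\n", max(x$damage$omega$values)))
  }
  invisible(x)
}
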