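#' Process configuration for a coupled run
#'
#' Collects geometry, grid resolution, electrical drive, timing, initial
#' temperature and thermal boundary condition for one simulated ohmic
#' process. Defaults reproduce the packaged reference process: a mashed
#' potato cylinder of radius 0.010 m with a 0.20 m electrode gap, 100 V
#' applied, starting at 279.15 K, 150 s duration at dt = 0.5 s, on a
#' 16 x 16 cell mesh.
#'
#' @param geometry a [cylinder_geometry()].
#' @param nr,nz grid resolution (radial x axial cells).
#' @param applied_voltage electrode potential difference, V.
#' @param drive_mode `"constant_voltage"` or `"constant_power"`.
#' @param target_power set point for constant-power drive, W. `NULL` (the
#'   default) pins the power at the value dissipated on the first step.
#' @param duration simulated process time, s.
#' @param dt time step, s (must not exceed `duration`).
#' @param T0 uniform initial temperature, K.
#' @param thermal_bc a [thermal_bc()].
#' @param snapshot_interval interval between stored field snapshots, s
#'   (`Inf` keeps only the final fields).
#' @param max_temperature boiling guard, K: the run aborts if any cell
#'   exceeds it, since the property table and the single-phase model are
#'   invalid past boiling.
#' @return An object of class `process_config`.
#' @export
process_config <- function(geometry = cylinder_geometry(),
                           nr = 16L, nz = 16L,
                           applied_voltage = 100,
                           drive_mode = c("constant_voltage", "constant_power"),
                           target_power = NULL,
                           duration = 150, dt = 0.5,
                           T0 = 279.15,
                           thermal_bc = ohmicheat::thermal_bc(),
                           snapshot_interval = Inf,
                           max_temperature = 373.15) {
  drive_mode <- match.arg(drive_mode)
  stopifnot(inherits(geometry, "cylinder_geometry"),
            inherits(thermal_bc, "thermal_bc"))
  if (!is.finite(duration) || duration <= 0) stop("process_config: duration must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("process_config: dt must be > 0")
  if (dt > duration) stop("process_config: dt must not exceed duration")
  if (!is.finite(T0) || T0 <= 0) stop("process_config: T0 must be a positive temperature in K")
  if (!is.finite(applied_voltage) || applied_voltage <= 0)
    stop("process_config: applied_voltage must be > 0")
  if (!is.null(target_power) && (!is.finite(target_power) || target_power <= 0))
    stop("process_config: target_power must be > 0 when given")
  structure(list(geometry = geometry, nr = as.integer(nr), nz = as.integer(nz),
                 applied_voltage = applied_voltage, drive_mode = drive_mode,
                 target_power = target_power,
                 duration = duration, dt = dt, T0 = T0,
                 thermal_bc = thermal_bc,
                 snapshot_interval = snapshot_interval,
                 max_temperature = max_temperature),
            class = "process_config")
}

#' Rescale the Joule source for constant-power drive
#'
#' Multiplies the source field by `target_power / current_power` and reports
#' the equivalent applied voltage `V * sqrt(ratio)` (the source scales with
#' the square of the voltage).
#'
#' @param Q Joule source per cell, W m^-3.
#' @param mesh the mesh.
#' @param target_power desired total power, W.
#' @param applied_voltage voltage that produced `Q`, V.
#' @return A list with `Q` (rescaled field), `voltage` (equivalent applied
#'   voltage) and `ratio`.
#' @export
rescale_for_constant_power <- function(Q, mesh, target_power, applied_voltage) {
  cur <- total_power(mesh, Q)
  if (!is.finite(cur) || cur <= 0)
    stop("rescale_for_constant_power: current total power must be > 0")
  ratio <- target_power / cur
  list(Q = Q * ratio, voltage = applied_voltage * sqrt(ratio), ratio = ratio)
}

#' Run a coupled electro-thermal(-microbial) simulation
#'
#' Advances the loosely coupled system in time: at each step the material
#' properties are evaluated at the current temperatures, the quasistatic
#' potential is solved, the Joule source is computed (and rescaled in
#' constant-power drive), the temperature field takes one implicit step, and
#' the per-cell lethality integral is updated. The quasistatic potential
#' adapts instantly to the temperature field, and at the default
#' dt = 0.5 s the per-step property change is small, so one potential solve
#' per step suffices; an optional within-step fixed-point iteration on the
#' property nonlinearity is available for convergence studies.
#'
#' @param config a [process_config()].
#' @param table a [property_table()]; defaults to the packaged
#'   mashed-potato table.
#' @param kinetics optional [kinetics_params()]; when supplied, accumulated
#'   lethality is tracked per cell and the cold spot (minimum-F cell) is
#'   traced.
#' @param extend_to_target if `TRUE` (requires `kinetics`), the run
#'   continues past `config$duration` until the minimum log reduction
#'   reaches the kinetics target, up to `max_duration`.
#' @param max_duration hard cap for `extend_to_target`, s.
#' @param picard_tol if non-`NULL`, iterate properties/potential/thermal
#'   step within each step until the max temperature change between
#'   iterates falls below this tolerance (K).
#' @return An object of class `ohm_trace`: per-step time series (`times`,
#'   `T_min`, `T_max`, `T_mean`, `power_W`, `voltage_V`, `F_min`,
#'   `log_red_min`, `cold_cell`), final fields (`T`, `V`, `Q`, `F`), the
#'   `mesh`, `snapshots`, and `t_target` (time to the kinetics target, or
#'   `NA` if not reached/tracked).
#' @export
run_simulation <- function(config, table = default_property_table(),
                           kinetics = NULL,
                           extend_to_target = FALSE, max_duration = 3600,
                           picard_tol = NULL) {
  stopifnot(inherits(config, "process_config"), inherits(table, "property_table"))
  if (extend_to_target && is.null(kinetics))
    stop("run_simulation: extend_to_target requires kinetics")
  if (!is.null(kinetics)) stopifnot(inherits(kinetics, "kinetics_params"))
  mesh <- build_mesh(config$geometry, config$nr, config$nz)
  n <- mesh$ncell
  dt <- config$dt
  n_base <- ceiling(config$duration / dt - 1e-9)
  n_max <- if (extend_to_target) ceiling(max_duration / dt - 1e-9) else n_base
  ebc <- electric_bc(config$applied_voltage, config$drive_mode)
  bc <- config$thermal_bc

  T <- rep(config$T0, n)
  F <- numeric(n)
  target_power <- config$target_power

  times <- numeric(n_max + 1L)
  T_min <- T_max <- T_mean <- power_W <- voltage_V <- numeric(n_max + 1L)
  F_min <- log_red_min <- numeric(n_max + 1L)
  cold_cell <- integer(n_max + 1L)
  snapshots <- list()
  next_snap <- 0
  floor_T <- min(config$T0, bc$T_inf) - 5

  record <- function(k, t, T, F, P, volt) {
    times[k] <<- t
    T_min[k] <<- min(T); T_max[k] <<- max(T); T_mean[k] <<- mean(T)
    power_W[k] <<- P; voltage_V[k] <<- volt
    F_min[k] <<- min(F)
    log_red_min[k] <<- if (is.null(kinetics)) NA_real_ else min(F) / kinetics$D_ref
    cold_cell[k] <<- which.min(F)
  }

  step_fields <- function(T) {
    props <- property_fields(table, T)
    V <- solve_potential(mesh, props$electrical_conductivity, ebc)
    Q <- joule_source(mesh, props$electrical_conductivity, V)
    volt <- config$applied_voltage
    if (config$drive_mode == "constant_power") {
      if (is.null(target_power)) target_power <<- total_power(mesh, Q)
      rs <- rescale_for_constant_power(Q, mesh, target_power, volt)
      Q <- rs$Q; volt <- rs$voltage
    }
    list(props = props, V = V, Q = Q, volt = volt)
  }

  sf <- step_fields(T)
  record(1L, 0, T, F, total_power(mesh, sf$Q), sf$volt)
  if (is.finite(config$snapshot_interval)) {
    snapshots[[length(snapshots) + 1L]] <-
      list(time_s = 0, T = T, V = sf$V, Q = sf$Q, F = F)
    next_snap <- config$snapshot_interval
  }

  k <- 1L
  t <- 0
  while (k <= n_max) {
    sf <- step_fields(T)
    T_new <- step_temperature(mesh, T, sf$Q, sf$props, bc, dt)
    if (!is.null(picard_tol)) {
      for (it in 1:20) {
        sf2 <- step_fields(T_new)
        T_it <- step_temperature(mesh, T, sf2$Q, sf2$props, bc, dt)
        delta <- max(abs(T_it - T_new))
        T_new <- T_it; sf <- sf2
        if (delta < picard_tol) break
      }
    }
    if (max(T_new) > config$max_temperature)
      stop(sprintf(paste0("run_simulation: boiling guard tripped at t = %.1f s ",
                          "(max T = %.2f K > %.2f K); the property table and the ",
                          "single-phase model are invalid past boiling"),
                   t + dt, max(T_new), config$max_temperature))
    if (min(T_new) < floor_T)
      stop("run_simulation: temperature sanity check failed (undershoot below initial/ambient)")
    if (!is.null(kinetics))
      F <- accumulate_lethality(F, T, T_new, kinetics, dt)
    T <- T_new
    t <- t + dt
    k <- k + 1L
    record(k, t, T, F, total_power(mesh, sf$Q), sf$volt)
    if (is.finite(config$snapshot_interval) && t >= next_snap - 1e-9) {
      snapshots[[length(snapshots) + 1L]] <-
        list(time_s = t, T = T, V = sf$V, Q = sf$Q, F = F)
      next_snap <- next_snap + config$snapshot_interval
    }
    reached <- !is.null(kinetics) &&
      min(F) / kinetics$D_ref >= kinetics$target_log_reduction
    if (k > n_base && !extend_to_target) break
    if (extend_to_target && reached && k > 1L) break
  }

  keep <- seq_len(k)
  t_target <- if (is.null(kinetics)) NA_real_ else
    time_to_target(times[keep], log_red_min[keep], kinetics$target_log_reduction)
  sf_end <- step_fields(T)
  structure(list(times = times[keep], T_min = T_min[keep], T_max = T_max[keep],
                 T_mean = T_mean[keep], power_W = power_W[keep],
                 voltage_V = voltage_V[keep],
                 F_min = F_min[keep], log_red_min = log_red_min[keep],
                 cold_cell = cold_cell[keep],
                 T = T, V = sf_end$V, Q = sf_end$Q, F = F,
                 mesh = mesh, config = config, kinetics = kinetics,
                 snapshots = snapshots, t_target = t_target),
            class = "ohm_trace")
}

#' @export
print.ohm_trace <- function(x, ...) {
  cat(sprintf("Ohmic heating run: %.1f s simulated, %d steps, %d x %d mesh\n",
              max(x$times), length(x$times) - 1L, x$mesh$nr, x$mesh$nz))
  cat(sprintf("  final T: min %.2f / mean %.2f / max %.2f K; final power %.1f W\n",
              min(x$T), mean(x$T), max(x$T), x$power_W[length(x$power_W)]))
  if (!is.null(x$kinetics))
    cat(sprintf("  min log reduction %.2f; time to %gD: %s\n",
                min(x$F) / x$kinetics$D_ref, x$kinetics$target_log_reduction,
                if (is.na(x$t_target)) "not reached" else sprintf("%.1f s", x$t_target)))
  invisible(x)
}

#' Lumped (0-D) heating trajectory for an insulated sample
#'
#' Verification oracle: with insulated boundaries and a uniform initial
#' state the exact solution of the coupled problem is spatially uniform and
#' obeys the scalar balance `VHC(T) dT/dt = sigma(T) (V0/L)^2`. Solved here
#' with a high-accuracy adaptive ODE integrator.
#'
#' @param table a [property_table()].
#' @param V0 applied voltage, V.
#' @param L electrode gap, m.
#' @param T0 initial temperature, K.
#' @param duration trajectory length, s.
#' @param times optional explicit output times, s.
#' @return A data.frame with columns `time_s` and `temperature_K`.
#' @export
lumped_ode <- function(table, V0, L, T0, duration, times = NULL) {
  stopifnot(inherits(table, "property_table"))
  if (is.null(times)) times <- seq(0, duration, length.out = 301L)
  E2 <- (V0 / L)^2
  rhs <- function(t, y, parms) {
    list(evaluate_property(table, "electrical_conductivity", y) * E2 /
           evaluate_property(table, "volumetric_heat_capacity", y))
  }
  out <- deSolve::ode(y = c(T = T0), times = times, func = rhs,
                      rtol = 1e-10, atol = 1e-8)
  data.frame(time_s = out[, 1], temperature_K = out[, 2])
}
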