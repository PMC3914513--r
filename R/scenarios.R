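#' Define a sensitivity scenario
#'
#' A scenario perturbs the reference process through the external heat
#' exchange (U, T_inf), a uniform scale on the electrical conductivity
#' curve, and the drive mode, leaving everything else at the base
#' configuration.
#'
#' @param name scenario label.
#' @param U overall heat transfer coefficient, W m^-2 K^-1.
#' @param T_inf external temperature, K.
#' @param sigma_scale uniform factor on the electrical conductivity (> 0).
#' @param drive_mode `"constant_voltage"` or `"constant_power"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, U = 0, T_inf = 286.15, sigma_scale = 1,
                          drive_mode = "constant_voltage") {
  if (!is.finite(sigma_scale) || sigma_scale <= 0)
    stop("scenario_spec: sigma_scale must be > 0")
  structure(list(name = as.character(name), U = U, T_inf = T_inf,
                 sigma_scale = sigma_scale, drive_mode = drive_mode),
            class = "scenario_spec")
}

#' The seven built-in process-sensitivity cases
#'
#' C1 is the insulated control; C2/C3 perturb the electrical conductivity by
#' +/-10% (still insulated); C4-C7 combine heat-loss coefficients of 5 and
#' 15 W m^-2 K^-1 with cold (286.15 K) and warm (314.15 K) surroundings.
#' All run at 100 V constant voltage.
#'
#' @return A named list of seven [scenario_spec()]s, C1 first (the control).
#' @export
builtin_cases <- function() {
  specs <- list(
    scenario_spec("C1", U = 0),
    scenario_spec("C2", U = 0, sigma_scale = 1.10),
    scenario_spec("C3", U = 0, sigma_scale = 0.90),
    scenario_spec("C4", U = 5, T_inf = 286.15),
    scenario_spec("C5", U = 5, T_inf = 314.15),
    scenario_spec("C6", U = 15, T_inf = 286.15),
    scenario_spec("C7", U = 15, T_inf = 314.15))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Classify the cold-spot location of a lethality field
#'
#' The process-limiting location is the cell with the least accumulated
#' lethality. If the relative spread of F over the sample is below the
#' uniformity threshold the field is `"uniform"` (no meaningful cold spot,
#' as for a perfectly insulated cell). Otherwise the minimum-F cell is
#' classified `"exterior-corner"` when it lies in the outermost radial ring
#' within the outermost axial layers (the junction of an electrode with the
#' lateral surface), `"on-axis"` when it lies on the symmetry axis, and the
#' raw `"cell(i,j)"` location is reported otherwise.
#'
#' @param F accumulated lethality per cell, s.
#' @param mesh the mesh `F` lives on.
#' @param uniformity_threshold relative spread `(max - min)/max` below which
#'   the field counts as uniform (default 1%).
#' @return A character scalar.
#' @export
classify_cold_spot <- function(F, mesh, uniformity_threshold = 0.01) {
  stopifnot(inherits(mesh, "axisym_mesh"), length(F) == mesh$ncell)
  spread <- (max(F) - min(F)) / max(F)
  if (spread < uniformity_threshold) return("uniform")
  ij <- mesh_ij(mesh, which.min(F))
  band_r <- max(1L, ceiling(mesh$nr / 8))
  band_z <- max(1L, ceiling(mesh$nz / 8))
  corner <- ij$i > mesh$nr - band_r &&
    (ij$j <= band_z || ij$j > mesh$nz - band_z)
  if (corner) return("exterior-corner")
  if (ij$i == 1L) return("on-axis")
  sprintf("cell(%d,%d)", ij$i, ij$j)
}

#' Run a set of scenarios and build the comparison report
#'
#' Each scenario is simulated until the minimum log reduction reaches the
#' kinetics target (the simulated duration is auto-extended past the base
#' process time if needed, up to `max_duration`; a scenario that never
#' reaches the target is reported with `t12D_s = NA`, not an error). The
#' first scenario is the control against which percent changes are
#' computed.
#'
#' @param specs a list of [scenario_spec()]s; defaults to [builtin_cases()].
#' @param base a [process_config()] providing geometry, voltage, timing and
#'   initial temperature.
#' @param table a [property_table()].
#' @param kinetics a [kinetics_params()].
#' @param max_duration hard cap on auto-extension, s.
#' @return An object of class `ohm_report`: a data.frame with one row per
#'   scenario (`scenario`, `t12D_s`, `pct_vs_control`, `cold_spot_class`,
#'   `Tmin_K`, `Tmax_K`) and the individual run traces in attribute
#'   `traces`.
#' @export
run_suite <- function(specs = builtin_cases(), base = process_config(),
                      table = default_property_table(),
                      kinetics = kinetics_params(), max_duration = 3600) {
  stopifnot(length(specs) >= 1L)
  traces <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    sp <- specs[[s]]
    stopifnot(inherits(sp, "scenario_spec"))
    cfg <- base
    cfg$thermal_bc <- thermal_bc(U = sp$U, T_inf = sp$T_inf,
                                 faces = base$thermal_bc$faces)
    cfg$drive_mode <- sp$drive_mode
    tab <- scale_conductivity(table, sp$sigma_scale)
    tr <- run_simulation(cfg, tab, kinetics,
                         extend_to_target = TRUE, max_duration = max_duration)
    traces[[s]] <- tr
    rows[[s]] <- data.frame(
      scenario = sp$name,
      t12D_s = tr$t_target,
      cold_spot_class = classify_cold_spot(tr$F, tr$mesh),
      Tmin_K = min(tr$T), Tmax_K = max(tr$T),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  t_control <- report$t12D_s[1L]
  report$pct_vs_control <- 100 * (report$t12D_s - t_control) / t_control
  report <- report[, c("scenario", "t12D_s", "pct_vs_control",
                       "cold_spot_class", "Tmin_K", "Tmax_K")]
  names(traces) <- report$scenario
  structure(report, class = c("ohm_report", "data.frame"), traces = traces)
}

#' @export
print.ohm_report <- function(x, ...) {
  cat("Scenario report (control =", x$scenario[1L], ")\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}
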