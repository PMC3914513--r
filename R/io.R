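#' Load a simulation configuration file
#'
#' Reads a YAML configuration with sections `geometry`, `grid`, `process`,
#' `thermal_bc`, `kinetics`, `property_table` and `scenarios`. Every field
#' is optional — missing values fall back to the packaged reference process
#' (100 V, 279.15 K start, 150 s at dt = 0.5 s) — but unknown keys are an
#' error (never silently ignored), and invalid values are reported with
#' their exact field path.
#'
#' @param path path to the YAML file.
#' @param verbose if `TRUE`, echo the fully resolved configuration
#'   (including defaulted assumptions such as geometry and kinetics
#'   references) via `message()`.
#' @return A list with components `config` ([process_config()]), `kinetics`
#'   ([kinetics_params()]), `table` ([property_table()]) and `scenarios`
#'   (list of [scenario_spec()]s, or `NULL` if none were configured).
#' @export
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  .check_keys(raw, c("geometry", "grid", "process", "thermal_bc", "kinetics",
                     "property_table", "scenarios"), "")

  geo <- .section(raw, "geometry", c("radius", "length"))
  grid <- .section(raw, "grid", c("nr", "nz"))
  prc <- .section(raw, "process",
                  c("applied_voltage", "drive_mode", "target_power",
                    "duration", "dt", "T0", "snapshot_interval",
                    "max_temperature"))
  tbc <- .section(raw, "thermal_bc", c("U", "T_inf", "faces"))
  kin <- .section(raw, "kinetics", c("z", "D_ref", "T_ref", "target_log_reduction"))

  if (!is.null(tbc$U) && (!is.numeric(tbc$U) || tbc$U < 0))
    stop("invalid configuration: thermal_bc.U must be a number >= 0")

  bc <- .with_defaults(thermal_bc, list(U = tbc$U, T_inf = tbc$T_inf, faces = tbc$faces))
  geometry <- .with_defaults(cylinder_geometry,
                             list(radius = geo$radius, length = geo$length))
  config <- .with_defaults(process_config, c(
    list(geometry = geometry, thermal_bc = bc),
    list(nr = grid$nr, nz = grid$nz,
         applied_voltage = prc$applied_voltage, drive_mode = prc$drive_mode,
         target_power = prc$target_power, duration = prc$duration,
         dt = prc$dt, T0 = prc$T0, snapshot_interval = prc$snapshot_interval,
         max_temperature = prc$max_temperature)))
  kinetics <- .with_defaults(kinetics_params, kin)

  table <- if (is.null(raw$property_table)) default_property_table() else {
    p <- raw$property_table
    if (!is.character(p) || length(p) != 1L)
      stop("invalid configuration: property_table must be a file path")
    if (!file.exists(p) && file.exists(file.path(dirname(path), p)))
      p <- file.path(dirname(path), p)
    read_property_table(p)
  }

  scenarios <- NULL
  if (!is.null(raw$scenarios)) {
    if (identical(raw$scenarios, "builtin")) scenarios <- builtin_cases()
    else {
      scenarios <- lapply(seq_along(raw$scenarios), function(s) {
        sc <- raw$scenarios[[s]]
        .check_keys(sc, c("name", "U", "T_inf", "sigma_scale", "drive_mode"),
                    sprintf("scenarios[%d].", s))
        if (is.null(sc$name))
          stop(sprintf("invalid configuration: scenarios[%d].name is required", s))
        .with_defaults(scenario_spec, sc)
      })
      names(scenarios) <- vapply(scenarios, `[[`, "", "name")
    }
  }

  if (verbose) {
    message(sprintf(
      "config %s: R = %g m, L = %g m (assumed cell unless set), %d x %d grid",
      path, geometry$radius, geometry$length, config$nr, config$nz))
    message(sprintf(
      "  %g V %s, %g s at dt = %g s, T0 = %g K; U = %g W/m^2/K, T_inf = %g K",
      config$applied_voltage, config$drive_mode, config$duration, config$dt,
      config$T0, bc$U, bc$T_inf))
    message(sprintf(
      "  kinetics (assumed unless set): z = %g K, D_ref = %g s at T_ref = %g K, target %gD",
      kinetics$z, kinetics$D_ref, kinetics$T_ref, kinetics$target_log_reduction))
  }
  list(config = config, kinetics = kinetics, table = table, scenarios = scenarios)
}

.check_keys <- function(x, allowed, prefix) {
  if (is.null(x)) return(invisible())
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("invalid configuration: unknown key(s) %s",
                 paste0(prefix, bad, collapse = ", ")))
  invisible()
}

.section <- function(raw, name, allowed) {
  sec <- raw[[name]]
  .check_keys(sec, allowed, paste0(name, "."))
  if (is.null(sec)) list() else sec
}

# Call `fun` with only the non-NULL arguments, letting the constructor's own
# defaults and validation fill the rest.
.with_defaults <- function(fun, args) {
  args <- args[!vapply(args, is.null, TRUE)]
  do.call(fun, args)
}

.fmt <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a run's time series to CSV
#'
#' One row per time step with a unit-annotated header; floating point values
#' are written at full precision so re-runs are byte-identical.
#'
#' @param trace an `ohm_trace` from [run_simulation()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ohm_trace"))
  d <- data.frame(time_s = .fmt(trace$times),
                  T_min_K = .fmt(trace$T_min),
                  T_max_K = .fmt(trace$T_max),
                  T_mean_K = .fmt(trace$T_mean),
                  power_W = .fmt(trace$power_W),
                  voltage_V = .fmt(trace$voltage_V),
                  F_min_s = .fmt(trace$F_min),
                  log_reduction_min = .fmt(trace$log_red_min),
                  cold_cell = trace$cold_cell)
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a field snapshot as a legacy-ASCII VTK rectilinear grid
#'
#' Cell-centred scalar fields on the (r, z) section, readable by ParaView
#' and friends. The radial coordinate maps to x and the axial to y.
#'
#' @param mesh the mesh.
#' @param fields named list of cell fields (numeric vectors of length
#'   `mesh$ncell`), e.g. `list(T = ..., V = ..., Q = ..., F = ...)`.
#' @param path output file path.
#' @param time_s snapshot time stamp written into the header comment.
#' @return The path, invisibly.
#' @export
write_snapshot_vtk <- function(mesh, fields, path, time_s = NA_real_) {
  stopifnot(inherits(mesh, "axisym_mesh"), is.list(fields), length(fields) >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("ohmicheat axisymmetric snapshot t=%s s", .fmt(time_s)),
               "ASCII", "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", mesh$nr + 1L, mesh$nz + 1L),
               sprintf("X_COORDINATES %d double", mesh$nr + 1L),
               paste(.fmt(mesh$r_face), collapse = " "),
               sprintf("Y_COORDINATES %d double", mesh$nz + 1L),
               paste(.fmt(mesh$z_face), collapse = " "),
               "Z_COORDINATES 1 double", "0",
               sprintf("CELL_DATA %d", mesh$ncell)), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (length(v) != mesh$ncell)
      stop(sprintf("write_snapshot_vtk: field %s has wrong length", nm))
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
                 .fmt(v)), con)
  }
  invisible(path)
}

#' Write a scenario report to CSV
#'
#' @param report an `ohm_report` from [run_suite()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ohm_report"))
  d <- data.frame(scenario = report$scenario,
                  t12D_s = .fmt(report$t12D_s),
                  pct_vs_control = .fmt(report$pct_vs_control),
                  cold_spot_class = report$cold_spot_class,
                  Tmin_K = .fmt(report$Tmin_K),
                  Tmax_K = .fmt(report$Tmax_K))
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
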