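#' Temperature-dependent property table
#'
#' Bundles tabulated measurements of thermal conductivity, volumetric heat
#' capacity (VHC, the product rho*Cp) and electrical conductivity as functions
#' of temperature. Between tabulated points properties are interpolated
#' linearly; outside the tabulated range they are clamped to the nearest end
#' value, so a transient overshoot never produces a negative or unbounded
#' property.
#'
#' Temperatures are supplied in degrees Celsius (the unit property tables are
#' usually printed in) and converted to kelvin on construction; every other
#' function in the package works in kelvin.
#'
#' @param temperature_c numeric, tabulated temperatures in deg C, strictly
#'   increasing.
#' @param thermal_conductivity numeric, W m^-1 K^-1, one value per temperature.
#' @param volumetric_heat_capacity numeric, J m^-3 K^-1, one value per
#'   temperature.
#' @param electrical_conductivity numeric, S m^-1, one value per temperature.
#' @return An object of class `property_table`.
#' @seealso [default_property_table()] for the packaged mashed-potato table,
#'   [evaluate_property()], [read_property_table()].
#' @export
property_table <- function(temperature_c, thermal_conductivity,
                           volumetric_heat_capacity, electrical_conductivity) {
  temperature_c <- as.numeric(temperature_c)
  n <- length(temperature_c)
  if (n < 2L)
    stop("property_table: at least two tabulated temperatures are required")
  if (any(!is.finite(temperature_c)) || any(diff(temperature_c) <= 0))
    stop("property_table: temperatures must be finite and strictly increasing")
  props <- list(thermal_conductivity = as.numeric(thermal_conductivity),
                volumetric_heat_capacity = as.numeric(volumetric_heat_capacity),
                electrical_conductivity = as.numeric(electrical_conductivity))
  for (nm in names(props)) {
    v <- props[[nm]]
    if (length(v) != n)
      stop(sprintf("property_table: %s must have %d values (one per temperature)",
                   nm, n))
    if (any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("property_table: %s values must be finite and strictly positive", nm))
  }
  structure(list(temperature_K = temperature_c + 273.15,
                 thermal_conductivity = props$thermal_conductivity,
                 volumetric_heat_capacity = props$volumetric_heat_capacity,
                 electrical_conductivity = props$electrical_conductivity),
            class = "property_table")
}

#' Packaged mashed-potato property table
#'
#' The measured thermal conductivity, volumetric heat capacity and electrical
#' conductivity of mashed potatoes at 5, 25, 45, 65 and 85 deg C that the
#' simulator uses by default. All three properties increase with temperature
#' over this range; the coupling between the growing electrical conductivity
#' and the Joule source is what makes ohmic heating accelerate as the sample
#' warms.
#'
#' @return A `property_table` with five rows spanning 5-85 deg C.
#' @export
default_property_table <- function() {
  property_table(
    temperature_c            = c(5, 25, 45, 65, 85),
    thermal_conductivity     = c(0.409, 0.451, 0.490, 0.532, 0.571),
    volumetric_heat_capacity = c(3.339, 3.383, 3.441, 3.496, 3.589) * 1e6,
    electrical_conductivity  = c(1.228, 1.991, 2.756, 3.514, 4.278))
}

#' Read a property table from a columnar text file
#'
#' Expects a comma-separated file with a header row and columns `T_celsius`,
#' `lambda` (W m^-1 K^-1), `vhc_MJ` (MJ m^-3 K^-1) and `sigma` (S m^-1).
#'
#' @param path file path.
#' @return A `property_table`.
#' @export
read_property_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("property table file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("T_celsius", "lambda", "vhc_MJ", "sigma")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop(sprintf("property table %s: missing column(s) %s",
                 path, paste(missing, collapse = ", ")))
  property_table(d$T_celsius, d$lambda, d$vhc_MJ * 1e6, d$sigma)
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("Property table: %d points, %.2f-%.2f K\n",
              length(x$temperature_K), min(x$temperature_K), max(x$temperature_K)))
  print(data.frame(T_K = x$temperature_K,
                   lambda_W_mK = x$thermal_conductivity,
                   vhc_J_m3K = x$volumetric_heat_capacity,
                   sigma_S_m = x$electrical_conductivity), row.names = FALSE)
  invisible(x)
}

#' Evaluate a tabulated property at given temperatures
#'
#' Piecewise-linear interpolation between the tabulated points, with constant
#' (clamped) extrapolation outside the tabulated temperature range.
#'
#' @param table a [property_table()].
#' @param which one of `"thermal_conductivity"`,
#'   `"volumetric_heat_capacity"`, `"electrical_conductivity"`.
#' @param T temperatures in kelvin (vectorised).
#' @return Property values in SI units, same length as `T`.
#' @examples
#' tab <- default_property_table()
#' evaluate_property(tab, "electrical_conductivity", 298.15)  # 1.991 S/m
#' @export
evaluate_property <- function(table, which, T) {
  stopifnot(inherits(table, "property_table"))
  which <- match.arg(which, c("thermal_conductivity",
                              "volumetric_heat_capacity",
                              "electrical_conductivity"))
  if (length(T) == 0L) return(numeric(0))
  if (any(!is.finite(T)))
    stop("evaluate_property: temperatures must be finite")
  stats::approx(table$temperature_K, table[[which]], xout = T,
                method = "linear", rule = 2)$y
}

#' Evaluate all three properties over a temperature field
#'
#' @param table a [property_table()].
#' @param T_field numeric vector of cell temperatures in kelvin.
#' @return A list with components `thermal_conductivity`,
#'   `volumetric_heat_capacity` and `electrical_conductivity`, each a vector
#'   aligned with `T_field`.
#' @export
property_fields <- function(table, T_field) {
  list(thermal_conductivity =
         evaluate_property(table, "thermal_conductivity", T_field),
       volumetric_heat_capacity =
         evaluate_property(table, "volumetric_heat_capacity", T_field),
       electrical_conductivity =
         evaluate_property(table, "electrical_conductivity", T_field))
}

#' Uniformly scale the electrical conductivity of a table
#'
#' Multiplies the tabulated electrical conductivity by a constant factor,
#' leaving the thermal properties untouched. Used by the sensitivity
#' scenarios that perturb conductivity by +/-10%.
#'
#' @param table a [property_table()].
#' @param factor positive scale factor.
#' @return A new `property_table`.
#' @export
scale_conductivity <- function(table, factor) {
  stopifnot(inherits(table, "property_table"))
  if (!is.finite(factor) || factor <= 0)
    stop("scale_conductivity: factor must be positive")
  table$electrical_conductivity <- table$electrical_conductivity * factor
  table
}
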