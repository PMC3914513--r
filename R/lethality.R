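#' First-order thermal inactivation parameters
#'
#' Classical D/z kinetics: the decimal reduction time D(T) is the time at
#' temperature T needed to destroy one log cycle (90%) of the target
#' population, and the z-value is the temperature rise that shrinks D
#' tenfold. The defaults describe Escherichia coli O157:H7, the target
#' organism of the packaged scenarios: z = 10 deg C, with a reference
#' decimal reduction time of 60 s at 60 deg C (a standard literature value
#' for this organism in solid foods; configurable, since absolute process
#' times scale directly with it).
#'
#' @param z z-value, kelvin (equivalently deg C difference), > 0.
#' @param D_ref decimal reduction time at `T_ref`, seconds, > 0.
#' @param T_ref reference temperature, K.
#' @param target_log_reduction log reductions defining process completion
#'   (default 12, the classical 12D criterion).
#' @return An object of class `kinetics_params`.
#' @export
kinetics_params <- function(z = 10, D_ref = 60, T_ref = 333.15,
                            target_log_reduction = 12) {
  if (!is.finite(z) || z <= 0) stop("kinetics_params: z must be > 0")
  if (!is.finite(D_ref) || D_ref <= 0) stop("kinetics_params: D_ref must be > 0")
  if (!is.finite(T_ref) || T_ref <= 0) stop("kinetics_params: T_ref must be a positive temperature in K")
  if (!is.finite(target_log_reduction) || target_log_reduction <= 0)
    stop("kinetics_params: target_log_reduction must be > 0")
  structure(list(z = z, D_ref = D_ref, T_ref = T_ref,
                 target_log_reduction = target_log_reduction),
            class = "kinetics_params")
}

#' Decimal reduction time at a temperature
#'
#' `D(T) = D_ref * 10^((T_ref - T)/z)`: holding at `T_ref` for `D_ref`
#' seconds reduces the population by one log cycle; every `z` kelvin above
#' `T_ref` divides the required time by ten.
#'
#' @param params a [kinetics_params()].
#' @param T temperature(s), K.
#' @return D in seconds, same length as `T`.
#' @export
decimal_reduction_time <- function(params, T) {
  stopifnot(inherits(params, "kinetics_params"))
  params$D_ref * 10^((params$T_ref - T) / params$z)
}

#' Lethal rate relative to the reference temperature
#'
#' The integrand `10^((T - T_ref)/z)` of the accumulated lethality: one at
#' the reference temperature, ten one z-value above it.
#'
#' @inheritParams decimal_reduction_time
#' @return Dimensionless rate, same length as `T`.
#' @export
lethal_rate <- function(params, T) {
  stopifnot(inherits(params, "kinetics_params"))
  10^((T - params$T_ref) / params$z)
}

#' Accumulate lethality over one time step
#'
#' Adds the per-cell increment of the sterility factor
#' `F(t) = integral of 10^((T - T_ref)/z) dt` using the trapezoid rule on
#' the step's endpoint temperatures — consistent with the first-order time
#' accuracy of the thermal scheme. F has units of seconds (equivalent time
#' at `T_ref`); the delivered log reduction is `F / D_ref`.
#'
#' @param F accumulated lethality per cell so far, s (use zeros to start).
#' @param T_old,T_new temperatures at the start and end of the step, K.
#' @param params a [kinetics_params()].
#' @param dt step size, s (> 0).
#' @return Updated F, same length as the inputs.
#' @export
accumulate_lethality <- function(F, T_old, T_new, params, dt) {
  stopifnot(inherits(params, "kinetics_params"))
  if (!is.finite(dt) || dt <= 0) stop("accumulate_lethality: dt must be > 0")
  F + dt / 2 * (lethal_rate(params, T_old) + lethal_rate(params, T_new))
}

#' Log reduction delivered by an accumulated lethality
#'
#' @param F accumulated lethality, s.
#' @param params a [kinetics_params()].
#' @return `log10(N0/N) = F / D_ref`.
#' @export
log_reduction <- function(F, params) {
  stopifnot(inherits(params, "kinetics_params"))
  F / params$D_ref
}

#' Time at which a log-reduction history reaches the target
#'
#' Scans a nondecreasing history of the minimum-over-cells log reduction and
#' returns the first time the target is reached, linearly interpolated
#' within the bracketing step. Returns `NA_real_` if the run ends before the
#' target is attained.
#'
#' @param times sample times, s, strictly increasing.
#' @param log_red log-reduction values at `times`, nondecreasing.
#' @param target target log reduction; defaults to 12.
#' @return Crossing time in seconds, or `NA_real_`.
#' @export
time_to_target <- function(times, log_red, target = 12) {
  if (length(times) == 0L) stop("time_to_target: empty history")
  if (length(times) != length(log_red))
    stop("time_to_target: times and log_red lengths differ")
  if (any(diff(log_red) < -1e-12))
    stop("time_to_target: log-reduction history must be nondecreasing")
  k <- which(log_red >= target)
  if (!length(k)) return(NA_real_)
  k <- k[1L]
  if (k == 1L) return(times[1L])
  t0 <- times[k - 1L]; t1 <- times[k]
  y0 <- log_red[k - 1L]; y1 <- log_red[k]
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}

#' Survivor curve along a time-temperature profile
#'
#' Integrates the first-order decay `dN/dt = -(ln 10 / D(T)) N` along a
#' temperature history, which in closed form is
#' `N(t) = N0 * 10^(-F(t)/D_ref)` with F the accumulated lethality
#' (trapezoid rule between the profile's samples).
#'
#' @param N0 initial population (> 0).
#' @param times sample times, s, strictly increasing.
#' @param T_profile temperatures at `times`, K.
#' @param params a [kinetics_params()].
#' @return A data.frame with columns `time_s`, `temperature_K`, `F_s`,
#'   `log_reduction` and `N`. `N` is strictly nonincreasing.
#' @export
survivor_curve <- function(N0, times, T_profile, params) {
  stopifnot(inherits(params, "kinetics_params"))
  if (!is.finite(N0) || N0 <= 0) stop("survivor_curve: N0 must be > 0")
  if (length(times) != length(T_profile))
    stop("survivor_curve: times and T_profile lengths differ")
  if (length(times) < 1L) stop("survivor_curve: empty profile")
  if (any(diff(times) <= 0)) stop("survivor_curve: times must be strictly increasing")
  rate <- lethal_rate(params, T_profile)
  F <- c(0, cumsum(diff(times) * (rate[-length(rate)] + rate[-1L]) / 2))
  lr <- log_reduction(F, params)
  data.frame(time_s = times, temperature_K = T_profile, F_s = F,
             log_reduction = lr, N = N0 * 10^(-lr))
}
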