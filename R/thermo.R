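# Arrhenius analysis of slow-stage rate constants and transition-state
# (Eyring) thermodynamics per temperature.

#' Rate-constant series
#'
#' Slow-stage extraction rate constants measured at two or more
#' temperatures, the input of the Arrhenius analysis.
#'
#' @param temperature temperatures, by default in degrees Celsius
#'   (`unit = "celsius"`); stored internally in Kelvin.
#' @param k positive rate constants, in the configured rate unit
#'   (per minute by default throughout the package).
#' @param series_id label of the condition the series belongs to.
#' @param unit `"celsius"` (default) or `"kelvin"`.
#' @return An object of class `rate_series` with elements `T_K`, `k`,
#'   `series_id`.
#' @examples
#' rate_series(c(30, 40, 50), c(1.33e-3, 1.60e-3, 1.87e-3), "hep2c/50%")
#' @export
rate_series <- function(temperature, k, series_id = "series",
                        unit = c("celsius", "kelvin")) {
  unit <- match.arg(unit)
  if (length(temperature) != length(k))
    stop_ec("`temperature` and `k` lengths differ", class = "value_error")
  if (length(unique(temperature)) < 2L)
    stop_ec("a rate series needs at least 2 distinct temperatures",
            class = "value_error")
  if (any(k <= 0))
    stop_ec("rate constants must be positive", class = "value_error")
  T_K <- if (unit == "celsius") celsius_to_kelvin(temperature)
         else as.numeric(temperature)
  if (any(T_K <= 0))
    stop_ec("absolute temperature must be positive", class = "value_error")
  structure(list(T_K = T_K, k = as.numeric(k), series_id = series_id),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat("Rate series", x$series_id, "\n")
  print(data.frame(T_K = x$T_K, k = x$k))
  invisible(x)
}

#' Arrhenius regression
#'
#' Least squares of `ln k` on `1/T`: the slope is `-Ea/R` and the intercept
#' `ln A`. With `two_point = TRUE` only the coldest and hottest entries are
#' used (the closed-form endpoint slope). A negative activation energy is
#' physically odd but not invalid and is returned with a warning.
#'
#' @param rs a [rate_series()].
#' @param two_point use only the two extreme temperatures.
#' @return An `arrhenius_result` with `Ea` (kJ/mol), `lnA` (log of the
#'   pre-exponential factor, same rate unit as `k`) and `r2`.
#' @examples
#' rs <- rate_series(c(30, 40, 50), c(1.33e-3, 1.60e-3, 1.87e-3))
#' fit_arrhenius(rs)$Ea
#' @export
fit_arrhenius <- function(rs, two_point = FALSE) {
  stopifnot(inherits(rs, "rate_series"))
  T_K <- rs$T_K
  k <- rs$k
  if (two_point) {
    sel <- c(which.min(T_K), which.max(T_K))
    T_K <- T_K[sel]
    k <- k[sel]
  }
  x <- 1 / T_K
  y <- log(k)
  fit <- lm(y ~ x)
  slope <- coef(fit)[[2L]]
  Ea <- -slope * .R_GAS / 1000
  if (Ea < -1e-10) warning("negative activation energy")
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  structure(list(Ea = Ea, lnA = coef(fit)[[1L]], r2 = r2,
                 R = .R_GAS, series_id = rs$series_id,
                 two_point = two_point),
            class = "arrhenius_result")
}

#' @export
print.arrhenius_result <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%s): Ea = %.3f kJ/mol, lnA = %.3f, R2 = %.4f\n",
              x$series_id, x$Ea, x$lnA, x$r2))
  invisible(x)
}

#' Activation enthalpy
#'
#' \eqn{\Delta H^* = E_a - RT}, in kJ/mol.
#'
#' @param Ea activation energy, kJ/mol.
#' @param T absolute temperature, Kelvin.
#' @return Activation enthalpy, kJ/mol.
#' @examples
#' activation_enthalpy(26.57, 323.15)
#' @export
activation_enthalpy <- function(Ea, T) {
  stopifnot(all(T > 0))
  Ea - .R_GAS * T / 1000
}

#' Activation entropy (Eyring relation)
#'
#' Solves the Eyring equation
#' \eqn{k = (k_B T / h) \exp(\Delta S^*/R) \exp(-\Delta H^*/RT)} for the
#' activation entropy:
#' \deqn{\Delta S^* = R [\ln(k h / (k_B T)) + \Delta H^*/(RT)].}
#' The numerical value depends on the unit of `k`; `rate_unit` states the
#' unit in which the Eyring frequency comparison is made. Rate constants are
#' passed in per-minute (the package-wide convention) and converted to
#' per-second first when `rate_unit = "per_second"`.
#'
#' @param k slow-stage rate constant, per minute.
#' @param T absolute temperature, Kelvin.
#' @param dH activation enthalpy, kJ/mol.
#' @param rate_unit `"per_minute"` (default) or `"per_second"`.
#' @return Activation entropy, J/(K mol).
#' @examples
#' activation_entropy(2.46e-3, 303.15, 8.01)
#' @export
activation_entropy <- function(k, T, dH,
                               rate_unit = c("per_minute", "per_second")) {
  rate_unit <- match.arg(rate_unit)
  stopifnot(all(k > 0), all(T > 0))
  k_eff <- if (rate_unit == "per_second") k / 60 else k
  .R_GAS * (log(k_eff * .H_PLANCK / (.K_BOLTZMANN * T)) +
              1000 * dH / (.R_GAS * T))
}

#' Gibbs energy of activation
#'
#' \eqn{\Delta G^* = \Delta H^* - T \Delta S^*}, with \eqn{\Delta H^*} in
#' kJ/mol and \eqn{\Delta S^*} in J/(K mol); the result is in kJ/mol.
#'
#' @param dH activation enthalpy, kJ/mol.
#' @param dS activation entropy, J/(K mol).
#' @param T absolute temperature, Kelvin.
#' @return Gibbs energy of activation, kJ/mol.
#' @examples
#' gibbs_activation(6.52, -277.95, 323.15)
#' @export
gibbs_activation <- function(dH, dS, T) {
  stopifnot(all(T > 0))
  dH - T * dS / 1000
}

#' Full transition-state analysis of a rate series
#'
#' Chains the Arrhenius regression with the per-temperature transition-state
#' parameters: for every (T, k) entry, \eqn{\Delta H^* = E_a - RT},
#' \eqn{\Delta S^*} from the Eyring relation, and
#' \eqn{\Delta G^* = \Delta H^* - T\Delta S^*}. Positive \eqn{\Delta H^*}
#' marks the process endothermic; positive \eqn{\Delta G^*} marks it
#' non-spontaneous.
#'
#' @param rs a [rate_series()] with rate constants per minute.
#' @param config a [run_config()]; supplies `rate_unit`.
#' @param two_point passed to [fit_arrhenius()].
#' @return An `activation_thermo`: the `arrhenius_result` plus a data frame
#'   with columns `T_K`, `k`, `dH_kJ_mol`, `dS_J_K_mol`, `dG_kJ_mol`,
#'   `endothermic`, `spontaneous`.
#' @examples
#' rs <- rate_series(c(30, 40, 50), c(1.33e-3, 1.60e-3, 1.87e-3))
#' activation_parameters(rs)
#' @export
activation_parameters <- function(rs, config = run_config(),
                                  two_point = FALSE) {
  arr <- fit_arrhenius(rs, two_point = two_point)
  dH <- activation_enthalpy(arr$Ea, rs$T_K)
  dS <- activation_entropy(rs$k, rs$T_K, dH, rate_unit = config$rate_unit)
  dG <- gibbs_activation(dH, dS, rs$T_K)
  structure(
    list(arrhenius = arr,
         table = data.frame(T_K = rs$T_K, k = rs$k,
                            Ea_kJ_mol = arr$Ea,
                            dH_kJ_mol = dH, dS_J_K_mol = dS, dG_kJ_mol = dG,
                            endothermic = dH > 0, spontaneous = dG < 0)),
    class = "activation_thermo")
}

#' @export
print.activation_thermo <- function(x, ...) {
  print(x$arrhenius)
  print(x$table, digits = 5, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.activation_thermo <- function(x, ...) x$table
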