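#' Analysis configuration
#'
#' Bundles the handful of conventions shared by all pipeline stages: the
#' significance level used for model reduction, the unit in which slow-stage
#' rate constants are expressed, the sum-of-squares convention of the effect
#' ANOVA, the RNG seed for synthetic data, and the concentration scale used
#' when interpolating IC50 values.
#'
#' @param alpha significance level for term retention, in (0, 1).
#' @param rate_unit unit of rate constants entering the transition-state
#'   equations: `"per_minute"` (default; extraction time courses are sampled
#'   in minutes) or `"per_second"`.
#' @param ss_convention effect sum-of-squares convention:
#'   `"paper_runs"` (default) computes `SS = n_runs * b^2` from the design
#'   runs, `"total_observations"` uses `SS = N_obs * b^2`.
#' @param seed non-negative integer seed for synthetic-data generation, or
#'   `NULL` to use the current RNG stream. The same seed and inputs give
#'   bit-identical outputs.
#' @param ic50_scale concentration scale for IC50 interpolation: `"log"`
#'   (default; dilution ladders are geometric) or `"linear"`.
#'
#' @return An object of class `run_config`.
#' @examples
#' run_config(alpha = 0.01, rate_unit = "per_second")
#' @export
run_config <- function(alpha = 0.05,
                       rate_unit = c("per_minute", "per_second"),
                       ss_convention = c("paper_runs", "total_observations"),
                       seed = NULL,
                       ic50_scale = c("log", "linear")) {
  check_number(alpha, "alpha", 0, 1, strict = TRUE)
  if (!is.null(seed)) {
    check_number(seed, "seed", lower = 0)
    if (seed != floor(seed))
      stop_ec("`seed` must be a non-negative integer", class = "value_error")
  }
  structure(
    list(alpha = alpha,
         rate_unit = match.arg(rate_unit),
         ss_convention = match.arg(ss_convention),
         seed = seed,
         ic50_scale = match.arg(ic50_scale)),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat("  alpha:        ", x$alpha, "\n")
  cat("  rate_unit:    ", x$rate_unit, "\n")
  cat("  ss_convention:", x$ss_convention, "\n")
  cat("  seed:         ", if (is.null(x$seed)) "<none>" else x$seed, "\n")
  cat("  ic50_scale:   ", x$ic50_scale, "\n")
  invisible(x)
}

#' Extraction condition
#'
#' A single set of extraction conditions: ethanol fraction of the solvent,
#' temperature (stored internally in Kelvin) and, optionally, the extraction
#' duration.
#'
#' @param ethanol_fraction ethanol concentration, percent v/v in \[0, 100\].
#' @param temperature temperature in degrees Celsius (must exceed absolute
#'   zero); converted internally with the 273.15 offset.
#' @param duration optional extraction time in minutes, non-negative.
#'
#' @return An object of class `extraction_condition` with elements
#'   `ethanol_fraction`, `temperature_K`, `temperature_C` and `duration`.
#' @examples
#' extraction_condition(30, 50, 80)
#' @export
extraction_condition <- function(ethanol_fraction, temperature,
                                 duration = NULL) {
  check_number(ethanol_fraction, "ethanol_fraction", 0, 100)
  check_number(temperature, "temperature", lower = -.C_TO_K, strict = TRUE)
  if (!is.null(duration)) check_number(duration, "duration", lower = 0)
  structure(
    list(ethanol_fraction = ethanol_fraction,
         temperature_K = celsius_to_kelvin(temperature),
         temperature_C = temperature,
         duration = duration),
    class = "extraction_condition")
}

#' @export
print.extraction_condition <- function(x, ...) {
  cat(sprintf("Extraction condition: %g%% ethanol, %g degC (%g K)%s\n",
              x$ethanol_fraction, x$temperature_C, x$temperature_K,
              if (is.null(x$duration)) "" else sprintf(", %g min", x$duration)))
  invisible(x)
}
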