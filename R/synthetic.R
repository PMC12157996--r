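# Synthetic-data generators: every input the pipeline consumes, with the
# statistical structure the analysis assumes. All generators are
# deterministic given a seed and leave the caller's RNG stream untouched.

#' Simulate a full factorial experiment
#'
#' Draws replicate responses from the coded first-order polynomial with all
#' interactions: `y = sum(beta_term * coded product) + N(0, sigma)` per
#' observation.
#'
#' @param beta named true coefficient vector (`b0`, `x1`, ..., full 2^k term
#'   set), e.g. [erica_effects()].
#' @param replicates replicate observations per run (default 2).
#' @param sigma replicate noise standard deviation (default 0.005, the
#'   response scale of a normalized yield).
#' @param seed RNG seed; identical seed and parameters give identical data.
#' @return A [factorial_dataset()].
#' @examples
#' gen_factorial(erica_effects("hep2c"), seed = 1)
#' @export
gen_factorial <- function(beta, replicates = 2, sigma = 0.005, seed = NULL) {
  k <- round(log2(length(beta)))
  if (length(beta) != 2^k || !setequal(names(beta), term_names(k)))
    stop_ec("`beta` must be a full 2^k coefficient set", class = "value_error")
  check_number(sigma, "sigma", lower = 0)
  check_number(replicates, "replicates", lower = 1)
  runs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  colnames(runs) <- paste0("x", seq_len(k))
  mu <- drop(coded_model_matrix(runs) %*% beta[term_names(k)])
  X <- runs[rep(seq_len(nrow(runs)), each = replicates), , drop = FALSE]
  mu_obs <- rep(mu, each = replicates)
  y <- with_seed(seed, mu_obs + rnorm(length(mu_obs), 0, sigma))
  design <- data.frame(X, response = y)
  factorial_dataset(design, factors = colnames(runs))
}

#' Simulate an extraction time course
#'
#' Evaluates a kinetic model on a time grid and adds Gaussian measurement
#' noise, clipping the result to \[0, 0.999\] so the linearized diffusion
#' fit stays defined.
#'
#' @param b washing coefficient in \[0, 1).
#' @param k slow-stage rate constant, per minute, positive.
#' @param model generating model: `"unsteady_diffusion"`
#'   (q = 1 - (1 - b) exp(-kt)) or `"ponomarev"` (q = min(b + kt, 1)).
#' @param times sampling times in minutes; defaults to the 7-point grid
#'   10, 15, 20, 30, 40, 60, 80 used in the bundled maceration study.
#' @param sigma yield noise standard deviation (default 0, noiseless).
#' @param seed RNG seed.
#' @param condition optional [extraction_condition()] attached to the curve.
#' @return A [time_course()].
#' @examples
#' gen_timecourse(b = 0.441, k = 2.46e-3, sigma = 0.01, seed = 7)
#' @export
gen_timecourse <- function(b, k, model = c("unsteady_diffusion", "ponomarev"),
                           times = c(10, 15, 20, 30, 40, 60, 80),
                           sigma = 0, seed = NULL, condition = NULL) {
  model <- match.arg(model)
  check_number(b, "b", 0, 1 - 1e-12)
  check_number(k, "k", lower = 0, strict = TRUE)
  check_number(sigma, "sigma", lower = 0)
  if (any(diff(times) <= 0))
    stop_ec("`times` must be strictly increasing", class = "value_error")
  q <- switch(model,
              unsteady_diffusion = 1 - (1 - b) * exp(-k * times),
              ponomarev = pmin(b + k * times, 1))
  q <- with_seed(seed, q + rnorm(length(q), 0, sigma))
  time_course(times, pmin(pmax(q, 0), 0.999), condition = condition)
}

#' Simulate an Arrhenius rate series
#'
#' `k(T) = A exp(-Ea / (R T))` with multiplicative lognormal noise
#' `exp(N(0, sigma_ln))`.
#'
#' @param Ea activation energy, kJ/mol, non-negative.
#' @param A pre-exponential factor, same rate unit as the returned `k`.
#' @param temperature temperatures (Celsius by default; see `unit`).
#' @param sigma_ln standard deviation of the log-rate noise (default 0).
#' @param seed RNG seed.
#' @param series_id label for the series.
#' @param unit `"celsius"` (default) or `"kelvin"`.
#' @return A [rate_series()].
#' @examples
#' gen_arrhenius(Ea = 13.89, A = 0.33, seed = 3)
#' @export
gen_arrhenius <- function(Ea, A, temperature = c(30, 40, 50),
                          sigma_ln = 0, seed = NULL, series_id = "synthetic",
                          unit = c("celsius", "kelvin")) {
  unit <- match.arg(unit)
  check_number(Ea, "Ea", lower = 0)
  check_number(A, "A", lower = 0, strict = TRUE)
  check_number(sigma_ln, "sigma_ln", lower = 0)
  T_K <- if (unit == "celsius") celsius_to_kelvin(temperature)
         else as.numeric(temperature)
  k <- A * exp(-1000 * Ea / (.R_GAS * T_K))
  k <- with_seed(seed, k * exp(rnorm(length(k), 0, sigma_ln)))
  rate_series(T_K, k, series_id = series_id, unit = "kelvin")
}

#' Simulate a dose-response curve
#'
#' Hill-type inhibition `I(c) = 100 c^h / (IC50^h + c^h) + N(0, sigma)`.
#'
#' @param ic50 true IC50, ug/mL.
#' @param hill Hill slope h (default 1).
#' @param concentration concentration ladder, ug/mL; defaults to an 8-point
#'   two-fold ladder centred on the IC50.
#' @param sigma inhibition noise standard deviation in percent (default 0).
#' @param seed RNG seed.
#' @param sample_id label.
#' @return A [dose_response_curve()].
#' @examples
#' gen_dose_response(ic50 = 14.29, seed = 2)
#' @export
gen_dose_response <- function(ic50, hill = 1,
                              concentration = ic50 * 2^seq(-3.5, 3.5, 1),
                              sigma = 0, seed = NULL, sample_id = "synthetic") {
  check_number(ic50, "ic50", lower = 0, strict = TRUE)
  check_number(hill, "hill", lower = 0, strict = TRUE)
  check_number(sigma, "sigma", lower = 0)
  inh <- 100 * concentration^hill / (ic50^hill + concentration^hill)
  inh <- with_seed(seed, inh + rnorm(length(inh), 0, sigma))
  dose_response_curve(concentration, inh, sample_id = sample_id)
}

#' Simulate a broth-microdilution series
#'
#' Flags each level of a two-fold ladder as inhibited when its concentration
#' is at or above the true MIC (a deterministic plate read).
#'
#' @param mic true minimum inhibitory concentration, ug/mL.
#' @param concentration two-fold ladder, ug/mL (default the 19.53-625
#'   six-level ladder of the bundled study).
#' @param strain label.
#' @return A [dilution_series()].
#' @examples
#' mic_from_series(gen_dilution(78.125))
#' @export
gen_dilution <- function(mic, concentration = 625 / 2^(5:0),
                         strain = "synthetic") {
  check_number(mic, "mic", lower = 0, strict = TRUE)
  dilution_series(concentration, concentration >= mic, strain = strain)
}

#' Simulate a condition-by-assay activity panel
#'
#' IC50s share a latent per-condition factor Z:
#' `IC50[cond, assay] = base[assay] * exp(loading[assay] * Z[cond] +
#' N(0, sigma))`, so a common loading induces positive cross-assay
#' correlation and zero loading gives independent columns.
#'
#' @param base_ic50 named vector of per-assay baseline IC50s, ug/mL.
#' @param loading per-assay loading on the latent condition factor; a single
#'   value is recycled.
#' @param n_conditions number of conditions (rows; default 9, a 3x3
#'   solvent-temperature grid).
#' @param sigma lognormal residual noise sd (default 0).
#' @param sd_z standard deviation of the latent condition factor (default
#'   0.25, matching the spread of printed extraction panels).
#' @param seed RNG seed.
#' @return An [activity_panel()].
#' @examples
#' gen_panel(c(LP = 22, DPPH = 20, Hep2c = 19), loading = 1, seed = 4)
#' @export
gen_panel <- function(base_ic50, loading = 1, n_conditions = 9,
                      sigma = 0, sd_z = 0.25, seed = NULL) {
  if (any(base_ic50 <= 0))
    stop_ec("baseline IC50s must be positive", class = "value_error")
  check_number(sigma, "sigma", lower = 0)
  loading <- rep_len(loading, length(base_ic50))
  m <- with_seed(seed, {
    z <- rnorm(n_conditions, 0, sd_z)
    eps <- matrix(rnorm(n_conditions * length(base_ic50), 0, sigma),
                  n_conditions)
    t(base_ic50 * t(exp(outer(z, loading) + eps)))
  })
  colnames(m) <- names(base_ic50) %||%
    paste0("assay", seq_along(base_ic50))
  rownames(m) <- paste0("cond", seq_len(n_conditions))
  activity_panel(m)
}
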