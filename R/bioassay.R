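# Bioassay reduction: IC50 interpolation, MIC reduction of two-fold dilution
# series, and Pearson correlation of condition x assay activity panels.

#' Dose-response curve
#'
#' Percent inhibition (cell survival or radical scavenging) measured over an
#' increasing concentration series.
#'
#' @param concentration concentrations in ug/mL, positive, strictly
#'   increasing, at least 2.
#' @param inhibition percent inhibition at each concentration.
#' @param sample_id label of the sample.
#' @return An object of class `dose_response_curve`.
#' @examples
#' dose_response_curve(c(10, 20, 40), c(30, 50, 70))
#' @export
dose_response_curve <- function(concentration, inhibition,
                                sample_id = "sample") {
  if (length(concentration) < 2L)
    stop_ec("a dose-response curve needs at least 2 points",
            class = "value_error")
  if (length(inhibition) != length(concentration))
    stop_ec("`concentration` and `inhibition` lengths differ",
            class = "value_error")
  if (any(concentration <= 0))
    stop_ec("concentrations must be positive", class = "value_error")
  if (any(diff(concentration) <= 0))
    stop_ec("concentrations must be strictly increasing",
            class = "value_error")
  structure(list(concentration = as.numeric(concentration),
                 inhibition = as.numeric(inhibition),
                 sample_id = sample_id),
            class = "dose_response_curve")
}

#' Interpolated IC50
#'
#' The concentration at which inhibition crosses 50%. An exact 50% reading
#' returns that concentration; otherwise the first bracketing pair of
#' adjacent points is interpolated linearly, on the log-concentration scale
#' by default (`ic50_scale` in the configuration) since dilution ladders are
#' geometric. A curve that never reaches 50% (or starts above it) yields a
#' censored result rather than a number.
#'
#' @param curve a [dose_response_curve()].
#' @param config a [run_config()]; supplies `ic50_scale`.
#' @return An `ic50_result` with `value` (ug/mL, NA when censored) and
#'   `censored` (`"none"`, `"above_max"`, `"below_min"`).
#' @examples
#' ic50_from_curve(dose_response_curve(c(10, 40), c(40, 60)))
#' @export
ic50_from_curve <- function(curve, config = run_config()) {
  stopifnot(inherits(curve, "dose_response_curve"))
  conc <- curve$concentration
  inh <- curve$inhibition

  hit <- which(inh == 50)
  if (length(hit)) {
    return(new_ic50(conc[hit[1L]], "none", curve$sample_id))
  }
  s <- sign(inh - 50)
  cross <- which(s[-1L] != s[-length(s)])
  if (!length(cross)) {
    if (all(inh < 50))
      return(new_ic50(NA_real_, "above_max", curve$sample_id,
                      bound = max(conc)))
    return(new_ic50(NA_real_, "below_min", curve$sample_id,
                    bound = min(conc)))
  }
  i <- cross[1L]
  x <- if (config$ic50_scale == "log") log(conc) else conc
  w <- (50 - inh[i]) / (inh[i + 1L] - inh[i])
  xi <- x[i] + w * (x[i + 1L] - x[i])
  value <- if (config$ic50_scale == "log") exp(xi) else xi
  new_ic50(value, "none", curve$sample_id)
}

new_ic50 <- function(value, censored, sample_id, bound = NA_real_) {
  structure(list(value = value, censored = censored, bound = bound,
                 sample_id = sample_id),
            class = "ic50_result")
}

#' @export
print.ic50_result <- function(x, ...) {
  lab <- switch(x$censored,
                none = sprintf("IC50 = %.4g ug/mL", x$value),
                above_max = sprintf("IC50 > %.4g ug/mL (censored)", x$bound),
                below_min = sprintf("IC50 < %.4g ug/mL (censored)", x$bound))
  cat(x$sample_id, ": ", lab, "\n", sep = "")
  invisible(x)
}

#' Two-fold dilution series
#'
#' Growth-inhibition flags over a geometric two-fold concentration ladder,
#' as read from a broth-microdilution plate. The ladder is validated as
#' two-fold within a 1% tolerance (printed concentrations are rounded).
#'
#' @param concentration concentrations in ug/mL forming a two-fold ladder.
#' @param inhibited logical (or 0/1) flag per concentration: growth
#'   inhibited?
#' @param strain label of the test strain.
#' @return An object of class `dilution_series`.
#' @examples
#' dilution_series(c(19.53, 39.06, 78.13, 156.25), c(0, 0, 1, 1))
#' @export
dilution_series <- function(concentration, inhibited, strain = "strain") {
  if (length(concentration) != length(inhibited))
    stop_ec("`concentration` and `inhibited` lengths differ",
            class = "value_error")
  ord <- order(concentration)
  conc <- as.numeric(concentration)[ord]
  inh <- as.logical(inhibited)[ord]
  if (any(conc <= 0))
    stop_ec("concentrations must be positive", class = "value_error")
  ratio <- conc[-1L] / conc[-length(conc)]
  if (any(abs(ratio - 2) > 0.02))
    stop_ec("concentrations do not form a two-fold ladder (ratio %s)",
            paste(round(ratio, 3), collapse = ", "), class = "value_error")
  structure(list(concentration = conc, inhibited = inh, strain = strain),
            class = "dilution_series")
}

#' Minimum inhibitory concentration
#'
#' The lowest concentration of the dilution series at which growth is
#' inhibited. If even the lowest tested concentration inhibits, the true MIC
#' may lie below it and the value is flagged `"at_or_below_min"`; if no
#' concentration inhibits, the result is censored `"above_max"`.
#'
#' @param series a [dilution_series()].
#' @return A `mic_result` with `value` (ug/mL; the maximum tested
#'   concentration when censored above) and `censored`
#'   (`"none"`, `"at_or_below_min"`, `"above_max"`).
#' @examples
#' mic_from_series(dilution_series(c(19.53, 39.06, 78.13), c(0, 1, 1)))
#' @export
mic_from_series <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  hit <- which(series$inhibited)
  if (!length(hit)) {
    res <- list(value = NA_real_, censored = "above_max",
                bound = max(series$concentration), strain = series$strain)
  } else if (hit[1L] == 1L) {
    res <- list(value = series$concentration[1L],
                censored = "at_or_below_min",
                bound = series$concentration[1L], strain = series$strain)
  } else {
    res <- list(value = series$concentration[hit[1L]], censored = "none",
                bound = NA_real_, strain = series$strain)
  }
  structure(res, class = "mic_result")
}

#' @export
print.mic_result <- function(x, ...) {
  lab <- switch(x$censored,
                none = sprintf("MIC = %.4g ug/mL", x$value),
                at_or_below_min = sprintf("MIC <= %.4g ug/mL", x$value),
                above_max = sprintf("MIC > %.4g ug/mL (censored)", x$bound))
  cat(x$strain, ": ", lab, "\n", sep = "")
  invisible(x)
}

#' Activity panel
#'
#' A complete condition-by-assay matrix of IC50 values (ug/mL), the input of
#' the cross-assay correlation analysis.
#'
#' @param x numeric matrix or data frame with one row per extraction
#'   condition and one column per assay; all entries positive, none missing.
#' @return An object of class `activity_panel` (a validated matrix).
#' @examples
#' activity_panel(erica_activity_panel())
#' @export
activity_panel <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop_ec("panel must be numeric", class = "value_error")
  if (anyNA(m)) stop_ec("panel has missing cells", class = "value_error")
  if (any(m <= 0)) stop_ec("IC50 values must be positive",
                           class = "value_error")
  if (nrow(m) < 3L)
    stop_ec("at least 3 conditions are needed for correlation",
            class = "value_error")
  if (is.null(colnames(m)))
    colnames(m) <- paste0("assay", seq_len(ncol(m)))
  structure(m, class = c("activity_panel", class(m)))
}

#' Pearson correlation matrix of an activity panel
#'
#' Pairwise Pearson correlation of the per-assay IC50 columns across
#' conditions. IC50s are correlated as given by default; `"reciprocal"`
#' (1/IC50, an activity scale) and `"log"` transforms are available. A
#' zero-variance column produces NaN entries with a warning.
#'
#' @param panel an [activity_panel()] (or matrix/data frame coercible to one).
#' @param transform `"none"` (default), `"reciprocal"` or `"log"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @examples
#' pearson_matrix(erica_activity_panel())["Hep2c", "RD"]
#' @export
pearson_matrix <- function(panel, transform = c("none", "reciprocal", "log")) {
  transform <- match.arg(transform)
  if (!inherits(panel, "activity_panel")) panel <- activity_panel(panel)
  m <- unclass(panel)
  m <- switch(transform, none = m, reciprocal = 1 / m, log = log(m))
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations undefined (NaN)")
  r <- suppressWarnings(cor(m))
  r[is.na(r)] <- NaN
  diag(r) <- ifelse(sds == 0, NaN, 1)
  r
}
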