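# Reference datasets from a maceration study of Erica carnea L. (spring
# heath): a 2^3 factorial extraction experiment with cytotoxic-activity
# yields against three tumour cell lines, slow-stage kinetic parameters for
# every solvent/temperature condition, transition-state parameters, and the
# IC50/MIC activity panels of the optimized extracts. All values are entered
# from the published summary tables; replicate-level measurements were not
# published (see `erica_pure_error()`).

erica_runs <- function() {
  data.frame(
    x1 = rep(c(-1, 1), 4),           # ethanol: 30 / 70 % v/v
    x2 = rep(c(-1, -1, 1, 1), 2),    # temperature: 30 / 50 degC
    x3 = rep(c(-1, 1), each = 4),    # time: 20 / 80 min
    hep2c = c(0.454, 0.442, 0.465, 0.450, 0.669, 0.606, 0.683, 0.659),
    rd    = c(0.558, 0.421, 0.570, 0.439, 0.692, 0.602, 0.716, 0.647),
    l2ob  = c(0.328, 0.181, 0.328, 0.192, 0.586, 0.391, 0.603, 0.448))
}

#' Factorial extraction experiment (reference data)
#'
#' The 2^3 full factorial maceration experiment on *Erica carnea* L.:
#' ethanol fraction (30/70% v/v), temperature (30/50 degC) and time
#' (20/80 min) in coded levels, with the published per-run mean yield of
#' cytotoxic activity against one of three cell lines as response. Only run
#' means were published, so the returned dataset carries one observation per
#' run; pair it with [erica_pure_error()] for the ANOVA.
#'
#' @param response `"hep2c"`, `"rd"` or `"l2ob"`.
#' @return A [factorial_dataset()].
#' @examples
#' fit_factorial(erica_factorial("hep2c"))
#' @export
erica_factorial <- function(response = c("hep2c", "rd", "l2ob")) {
  response <- match.arg(response)
  runs <- erica_runs()
  factorial_dataset(
    data.frame(runs[c("x1", "x2", "x3")], response = runs[[response]]),
    factors = c("x1", "x2", "x3"))
}

#' Published factorial regression coefficients (reference data)
#'
#' The reported coefficients of the coded first-order polynomial for the
#' yield of cytotoxic activity, as printed (4 decimals). The published
#' coefficient set reflects unpublished replicate data: for some terms it
#' differs from the contrast of the printed run means, so these vectors are
#' the canonical input for percentage-contribution, reduction and
#' prediction analyses of the reported models.
#'
#' @param response `"hep2c"`, `"rd"` or `"l2ob"`.
#' @return Named coefficient vector (`b0`, `x1`, ..., `x1x2x3`).
#' @examples
#' percentage_contribution(factorial_fit(erica_effects("hep2c")))
#' @export
erica_effects <- function(response = c("hep2c", "rd", "l2ob")) {
  response <- match.arg(response)
  tab <- list(
    hep2c = c(b0 = 0.5535, x1 = -0.0142, x2 = 0.0087, x3 = 0.1007,
              x1x2 = 0.0025, x1x3 = -0.0075, x2x3 = 0.0080, x1x2x3 = 0.0072),
    rd    = c(b0 = 0.5806, x1 = -0.0534, x2 = 0.0124, x3 = 0.0836,
              x1x2 = 0.0034, x1x3 = 0.0136, x2x3 = 0.0049, x1x2x3 = 0.0019),
    l2ob  = c(b0 = 0.3792, x1 = -0.0762, x2 = 0.0135, x3 = 0.1277,
              x1x2 = 0.0035, x1x3 = 0.0112, x2x3 = 0.0050, x1x2x3 = 0.0065))
  tab[[response]]
}

#' Published pure-error sums of squares (reference data)
#'
#' The replicate (pure-error) sum of squares and degrees of freedom of the
#' factorial ANOVA. The replicate observations themselves were not
#' published, so reproducing the reported ANOVA from the printed run means
#' requires injecting these values via the `error_ss`/`error_df` arguments
#' of [anova_factorial()].
#'
#' @param response `"hep2c"`, `"rd"` or `"l2ob"`.
#' @return List with `ss` and `df`.
#' @examples
#' erica_pure_error("hep2c")
#' @export
erica_pure_error <- function(response = c("hep2c", "rd", "l2ob")) {
  response <- match.arg(response)
  ss <- c(hep2c = 0.00016, rd = 0.00032, l2ob = 0.00048)
  list(ss = unname(ss[response]), df = 8)
}

#' Slow-stage kinetic parameters (reference data)
#'
#' Published washing coefficients and slow-stage rate constants of the
#' unsteady-state diffusion and Ponomarev models for every cell line,
#' ethanol fraction and temperature, with the reported goodness-of-fit
#' criteria. The raw time courses behind these fits were published only as
#' a figure, so these parameters serve as generating values for synthetic
#' curves and as inputs to the Arrhenius analysis, not as end-to-end fit
#' targets.
#'
#' @return Data frame with columns `cell_line`, `ethanol_pct`, `temp_C`,
#'   `model`, `b` (washing coefficient), `k` (1/min), `rms_percent`, `r2`.
#' @examples
#' subset(erica_kinetics(), cell_line == "hep2c" & model == "unsteady_diffusion")
#' @export
erica_kinetics <- function() {
  grid <- expand.grid(temp_C = c(30, 40, 50), ethanol_pct = c(30, 50, 70),
                      cell_line = c("hep2c", "rd", "l2ob"),
                      stringsAsFactors = FALSE)
  diff_par <- list(
    # b, k*1e3, rms, r2 triples per temperature, row order = grid order
    c(0.441, 2.46, 5.52, 0.9465), c(0.439, 2.64, 4.66, 0.9569),
    c(0.425, 2.87, 4.38, 0.9661), c(0.352, 1.33, 1.27, 0.8598),
    c(0.345, 1.60, 1.12, 0.8987), c(0.345, 1.87, 1.01, 0.9150),
    c(0.414, 1.76, 5.14, 0.9019), c(0.417, 1.90, 3.48, 0.9508),
    c(0.405, 2.28, 6.80, 0.8972),
    c(0.613, 2.08, 5.75, 0.8606), c(0.613, 2.24, 6.78, 0.8490),
    c(0.542, 2.79, 6.65, 0.8949), c(0.374, 1.42, 3.34, 0.9489),
    c(0.391, 1.58, 0.99, 0.8887), c(0.415, 1.78, 1.15, 0.8769),
    c(0.386, 1.91, 3.76, 0.9536), c(0.389, 2.08, 5.63, 0.9212),
    c(0.401, 2.18, 4.95, 0.9442),
    c(0.255, 3.27, 2.91, 0.9781), c(0.229, 3.48, 2.68, 0.9888),
    c(0.202, 3.69, 3.09, 0.9942), c(0.089, 2.11, 2.28, 0.9803),
    c(0.080, 2.45, 3.17, 0.9847), c(0.092, 2.69, 3.79, 0.9769),
    c(0.154, 1.74, 1.92, 0.9742), c(0.139, 2.17, 2.24, 0.9799),
    c(0.156, 2.67, 3.34, 0.9669))
  pono_par <- list(
    c(0.450, 2.35, 7.38, 0.9048), c(0.457, 2.45, 6.62, 0.9189),
    c(0.442, 2.61, 6.84, 0.9278), c(0.358, 1.66, 4.98, 0.8260),
    c(0.353, 1.94, 4.97, 0.8660), c(0.359, 2.15, 4.94, 0.8830),
    c(0.436, 1.78, 5.46, 0.8645), c(0.438, 1.87, 4.61, 0.9222),
    c(0.433, 2.20, 8.31, 0.8363),
    c(0.621, 1.69, 7.48, 0.8219), c(0.620, 1.74, 8.32, 0.8014),
    c(0.561, 1.88, 7.71, 0.8793), c(0.378, 1.40, 3.53, 0.9322),
    c(0.402, 1.53, 4.45, 0.8753), c(0.424, 1.68, 5.79, 0.8400),
    c(0.406, 1.62, 5.32, 0.9193), c(0.409, 1.71, 7.35, 0.8772),
    c(0.424, 1.78, 7.09, 0.8979),
    c(0.306, 3.41, 4.89, 0.9543), c(0.287, 3.65, 5.01, 0.9635),
    c(0.267, 3.89, 5.60, 0.9826), c(0.120, 2.75, 2.09, 0.9803),
    c(0.121, 3.21, 1.98, 0.9866), c(0.143, 3.61, 3.69, 0.9882),
    c(0.172, 2.62, 2.79, 0.9551), c(0.166, 3.11, 3.48, 0.9571),
    c(0.156, 3.64, 4.64, 0.9421))
  build <- function(pars, model) {
    m <- do.call(rbind, pars)
    data.frame(grid[c("cell_line", "ethanol_pct", "temp_C")], model = model,
               b = m[, 1], k = m[, 2] * 1e-3,
               rms_percent = m[, 3], r2 = m[, 4])
  }
  out <- rbind(build(diff_par, "unsteady_diffusion"),
               build(pono_par, "ponomarev"))
  rownames(out) <- NULL
  out
}

#' Slow-stage rate-constant series (reference data)
#'
#' Convenience accessor: the unsteady-state diffusion rate constants of one
#' cell line and ethanol fraction as a [rate_series()] over 30/40/50 degC,
#' ready for [fit_arrhenius()] or [activation_parameters()].
#'
#' @param cell_line `"hep2c"`, `"rd"` or `"l2ob"`.
#' @param ethanol_pct 30, 50 or 70.
#' @return A [rate_series()] (rates per minute).
#' @examples
#' fit_arrhenius(erica_rates("hep2c", 50))$Ea
#' @export
erica_rates <- function(cell_line = c("hep2c", "rd", "l2ob"),
                        ethanol_pct = c(30, 50, 70)) {
  cell_line <- match.arg(cell_line)
  ethanol_pct <- match.arg(as.character(ethanol_pct[1]), c("30", "50", "70"))
  kin <- erica_kinetics()
  sel <- kin$cell_line == cell_line & kin$ethanol_pct == as.numeric(ethanol_pct) &
    kin$model == "unsteady_diffusion"
  rate_series(kin$temp_C[sel], kin$k[sel],
              series_id = sprintf("%s/%s%%", cell_line, ethanol_pct))
}

#' Published transition-state parameters (reference data)
#'
#' The reported activation energy (one value per cell line and ethanol
#' fraction) and per-temperature activation enthalpy, entropy and Gibbs
#' energy of the slow extraction stage.
#'
#' @return Data frame with columns `cell_line`, `ethanol_pct`, `temp_C`,
#'   `Ea_kJ_mol`, `dH_kJ_mol`, `dS_J_K_mol`, `dG_kJ_mol`.
#' @examples
#' subset(erica_activation(), cell_line == "l2ob" & ethanol_pct == 30)
#' @export
erica_activation <- function() {
  grid <- expand.grid(temp_C = c(30, 40, 50), ethanol_pct = c(30, 50, 70),
                      cell_line = c("hep2c", "rd", "l2ob"),
                      stringsAsFactors = FALSE)
  Ea <- rep(c(10.52, 13.89, 26.57,       # hep2c 30/50/70% ethanol
              11.93, 9.21, 6.97,         # rd
              4.92, 9.91, 17.45),        # l2ob
            each = 3)
  vals <- rbind(
    c(8.01, -271.28, 90.20), c(7.92, -272.02, 93.07), c(7.84, -271.81, 95.63),
    c(11.37, -262.50, 90.91), c(11.29, -262.70, 93.51), c(11.20, -263.04, 96.17),
    c(24.25, -215.54, 89.36), c(23.97, -218.29, 92.21), c(23.88, -220.22, 95.02),
    c(9.41, -256.24, 89.78), c(9.33, -266.15, 92.63), c(9.25, -265.77, 95.09),
    c(6.69, -277.41, 90.74), c(6.60, -277.76, 93.54), c(6.52, -277.95, 96.30),
    c(4.45, -280.26, 89.26), c(4.37, -281.25, 92.40), c(4.29, -281.49, 95.21),
    c(2.40, -284.50, 88.61), c(2.32, -284.88, 91.49), c(2.24, -285.15, 94.34),
    c(7.39, -271.90, 89.77), c(7.31, -271.87, 92.40), c(7.22, -272.30, 95.18),
    c(14.93, -248.50, 90.23), c(14.85, -248.78, 92.72), c(14.77, -249.05, 95.21))
  data.frame(grid[c("cell_line", "ethanol_pct", "temp_C")],
             Ea_kJ_mol = Ea, dH_kJ_mol = vals[, 1],
             dS_J_K_mol = vals[, 2], dG_kJ_mol = vals[, 3])
}

#' Activity panel of the optimized extracts (reference data)
#'
#' Mean IC50 values (ug/mL) of the 80-min extracts over the nine
#' solvent-temperature conditions, across five antioxidant assays (lipid
#' peroxidation LP, DPPH and ABTS radical scavenging, metal chelation MC,
#' hydroxyl radical scavenging OH) and the three cytotoxicity assays.
#'
#' @return An [activity_panel()]: 9 conditions x 8 assays, with row names
#'   `<ethanol>%/<temp>C`.
#' @examples
#' pearson_matrix(erica_activity_panel())
#' @export
erica_activity_panel <- function() {
  m <- rbind(
    # LP, DPPH, MC, OH, ABTS, Hep2c, RD, L2OB per condition
    c(21.44, 19.35,  8.76, 13.54, 13.08, 16.33, 15.70, 25.21),
    c(20.01, 18.45,  7.66, 13.21, 12.61, 15.23, 14.19, 24.26),
    c(19.44, 16.55,  6.98, 13.09, 12.17, 14.29, 13.93, 22.23),
    c(27.60, 25.03, 16.01, 19.42, 17.41, 24.37, 22.44, 31.91),
    c(26.42, 24.43, 13.48, 17.19, 17.13, 23.38, 21.40, 30.48),
    c(25.25, 23.98, 12.45, 16.92, 16.83, 20.55, 17.49, 28.32),
    c(24.77, 22.14, 11.45, 14.22, 16.06, 22.22, 18.53, 29.55),
    c(24.23, 21.09, 10.98, 14.02, 15.51, 21.36, 17.88, 28.87),
    c(22.54, 20.94, 10.52, 13.97, 14.21, 20.24, 17.19, 27.88))
  dimnames(m) <- list(
    paste0(rep(c(30, 50, 70), each = 3), "%/", rep(c(30, 40, 50), 3), "C"),
    c("LP", "DPPH", "MC", "OH", "ABTS", "Hep2c", "RD", "L2OB"))
  activity_panel(m)
}

#' Antimicrobial MIC panel (reference data)
#'
#' Minimum inhibitory concentrations (ug/mL) of the extracts against eight
#' microbial strains over the nine solvent-temperature conditions, from
#' two-fold broth microdilution (ladder 19.53-625 ug/mL). Values equal to
#' the lowest tested concentration are lower bounds (the series was fully
#' inhibited).
#'
#' @return Data frame with `strain` and one column per condition
#'   (`E<ethanol>_T<temp>`).
#' @examples
#' erica_mic()
#' @export
erica_mic <- function() {
  strains <- c("Staphylococcus aureus ATCC 25923",
               "Klebsiella pneumoniae ATCC 13883",
               "Escherichia coli ATCC 25922",
               "Proteus vulgaris ATCC 13315",
               "Proteus mirabilis ATCC 14153",
               "Bacillus subtilis ATCC 6633",
               "Candida albicans ATCC 10231",
               "Aspergillus niger ATCC 16404")
  m <- rbind(
    c(19.53, 19.53, 19.53, 156.25, 156.25, 78.125, 39.1,   39.1,   39.1),
    c(19.53, 19.53, 19.53, 156.25, 156.25, 78.125, 78.125, 39.1,   39.1),
    c(19.53, 19.53, 19.53, 39.1,   39.1,   19.53,  19.53,  19.53,  19.53),
    c(19.53, 19.53, 19.53, 78.125, 78.125, 78.125, 39.1,   39.1,   39.1),
    c(19.53, 19.53, 19.53, 39.1,   19.53,  19.53,  19.53,  19.53,  19.53),
    c(19.53, 19.53, 19.53, 312.5,  312.5,  78.125, 39.1,   19.53,  19.53),
    c(19.53, 19.53, 19.53, 156.25, 156.25, 78.125, 78.125, 78.125, 78.125),
    c(19.53, 19.53, 19.53, 39.1,   19.53,  19.53,  19.53,  19.53,  19.53))
  out <- data.frame(strain = strains, m)
  names(out)[-1] <- paste0("E", rep(c(30, 50, 70), each = 3),
                           "_T", rep(c(30, 40, 50), 3))
  out
}
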