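# Extraction kinetics: unsteady-state diffusion and Ponomarev models fitted
# through their linearized forms, with goodness-of-fit on the original scale.

#' Extraction time course
#'
#' A normalized extraction curve: the yield fraction q(t) of the extractable
#' (activity-derived) solute recovered after t minutes, relative to its
#' equilibrium value. Yields must lie in \[0, 1\] and should be
#' non-decreasing; dips larger than 0.05 trigger a warning (measurement
#' noise) but are kept.
#'
#' @param time sampling times in minutes, strictly increasing, at least 3.
#' @param yield normalized yield fraction q at each time, in \[0, 1\].
#' @param condition optional [extraction_condition()] describing solvent and
#'   temperature.
#' @return An object of class `time_course`.
#' @examples
#' tc <- time_course(c(10, 20, 40, 80), c(0.46, 0.48, 0.51, 0.55))
#' @export
time_course <- function(time, yield, condition = NULL) {
  if (length(time) < 3L)
    stop_ec("a time course needs at least 3 points", class = "value_error")
  if (length(yield) != length(time))
    stop_ec("`time` and `yield` lengths differ", class = "value_error")
  if (any(diff(time) <= 0))
    stop_ec("`time` must be strictly increasing", class = "value_error")
  if (any(yield < 0 | yield > 1))
    stop_ec("yield fractions must lie in [0, 1]", class = "value_error")
  if (any(diff(yield) < -0.05))
    warning("yield decreases by more than 0.05 between samples")
  structure(list(time = as.numeric(time), yield = as.numeric(yield),
                 condition = condition),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Extraction time course (%d points, %g-%g min)\n",
              length(x$time), min(x$time), max(x$time)))
  print(data.frame(time_min = x$time, yield = x$yield))
  invisible(x)
}

new_kinetic_fit <- function(model, washing, rate, tc, flagged = FALSE,
                            n_used = length(tc$time)) {
  fit <- structure(
    list(model = model, washing_coefficient = washing, slow_rate = rate,
         r2 = NA_real_, rms_percent = NA_real_, flagged = flagged,
         n_used = n_used, time_course = tc),
    class = "kinetic_fit")
  gof <- goodness_of_fit(tc, fit)
  fit$r2 <- gof$r2
  fit$rms_percent <- gof$rms_percent
  fit
}

#' Fit the unsteady-state diffusion model
#'
#' Fits \eqn{q(t) = 1 - (1 - b) e^{-kt}} — a washing fraction `b` released
#' instantaneously followed by first-order diffusion at rate `k` (per
#' minute) — through its linearized form: least squares of `log(1 - q)` on
#' `t`, with slope `-k` and intercept `log(1 - b)`. Points with q >= 1 have
#' no linearized image and are dropped with a warning. A non-positive
#' estimated rate is returned flagged rather than failing.
#'
#' @param tc a [time_course()].
#' @return A `kinetic_fit` with `washing_coefficient` (b), `slow_rate` (k,
#'   1/min), original-scale `r2` and `rms_percent`, and a `flagged` marker.
#' @examples
#' tc <- gen_timecourse(b = 0.441, k = 2.46e-3)
#' fit_unsteady_diffusion(tc)
#' @export
fit_unsteady_diffusion <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  keep <- tc$yield < 1
  if (any(!keep))
    warning(sum(!keep), " point(s) with q >= 1 dropped before linearization")
  if (sum(keep) < 3L)
    stop_ec("fewer than 3 usable points for the diffusion fit",
            class = "fit_error")
  t_ <- tc$time[keep]
  z <- log(1 - tc$yield[keep])
  cf <- coef(lm(z ~ t_))
  k <- -cf[[2L]]
  b <- 1 - exp(cf[[1L]])
  flagged <- k <= 0
  if (flagged) warning("non-positive diffusion rate constant: fit flagged")
  new_kinetic_fit("unsteady_diffusion", b, k, tc, flagged, sum(keep))
}

#' Fit the Ponomarev model
#'
#' Fits the linear yield model \eqn{q(t) = b' + k' t}: ordinary least squares
#' of the yield fraction on time, with intercept `b'` (washing coefficient)
#' and slope `k'` (slow extraction rate, per minute). The fitted curve is
#' capped at q = 1 when predicting. `t_min` restricts the fit to the slow
#' phase (times >= t_min); by default all points are used.
#'
#' @param tc a [time_course()].
#' @param t_min optional lower time bound of the fit window, minutes.
#' @return A `kinetic_fit` (model `"ponomarev"`).
#' @examples
#' tc <- gen_timecourse(b = 0.450, k = 2.35e-3, model = "ponomarev")
#' fit_ponomarev(tc)
#' @export
fit_ponomarev <- function(tc, t_min = NULL) {
  stopifnot(inherits(tc, "time_course"))
  keep <- if (is.null(t_min)) rep(TRUE, length(tc$time)) else tc$time >= t_min
  if (sum(keep) < 2L)
    stop_ec("fewer than 2 points in the Ponomarev fit window",
            class = "fit_error")
  t_ <- tc$time[keep]
  q <- tc$yield[keep]
  cf <- coef(lm(q ~ t_))
  k <- cf[[2L]]
  flagged <- k <= 0
  if (flagged) warning("non-positive Ponomarev rate constant: fit flagged")
  new_kinetic_fit("ponomarev", cf[[1L]], k, tc, flagged, sum(keep))
}

#' Predicted yield curve of a kinetic fit
#'
#' @param object a `kinetic_fit`.
#' @param time times (minutes) at which to evaluate the model; defaults to
#'   the fitted time course's sampling times.
#' @param ... unused.
#' @return Numeric vector of predicted yield fractions.
#' @export
predict.kinetic_fit <- function(object, time = object$time_course$time, ...) {
  b <- object$washing_coefficient
  k <- object$slow_rate
  switch(object$model,
         unsteady_diffusion = 1 - (1 - b) * exp(-k * time),
         ponomarev = pmin(b + k * time, 1))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit: b = %.4g, k = %.4g 1/min, R2 = %.4f, RMS = %.2f%%%s\n",
              x$model, x$washing_coefficient, x$slow_rate, x$r2,
              x$rms_percent, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Goodness of fit of a kinetic model
#'
#' Both criteria are evaluated on the original (non-linearized) yield scale:
#' `r2 = 1 - sum((q - qhat)^2) / sum((q - mean(q))^2)` and the relative
#' root-mean-square deviation
#' `RMS% = 100 sqrt(mean(((qhat - q)/q)^2))`. Zero-yield points are excluded
#' from the RMS (relative error undefined) with a warning; a zero-variance
#' time course makes `r2` NaN with a warning.
#'
#' @param tc the [time_course()] the fit was computed on.
#' @param fit a `kinetic_fit`.
#' @return List with `r2` and `rms_percent`.
#' @examples
#' tc <- gen_timecourse(b = 0.441, k = 2.46e-3)
#' goodness_of_fit(tc, fit_ponomarev(tc))
#' @export
goodness_of_fit <- function(tc, fit) {
  stopifnot(inherits(tc, "time_course"), inherits(fit, "kinetic_fit"))
  q <- tc$yield
  qhat <- predict(fit, tc$time)
  sst <- sum((q - mean(q))^2)
  if (sst == 0) {
    warning("zero yield variance: R2 undefined (NaN)")
    r2 <- NaN
  } else {
    r2 <- 1 - sum((q - qhat)^2) / sst
  }
  nz <- q != 0
  if (any(!nz)) warning("zero-yield point(s) excluded from RMS")
  rms <- 100 * sqrt(mean(((qhat[nz] - q[nz]) / q[nz])^2))
  list(r2 = r2, rms_percent = rms)
}

#' Rank competing kinetic fits
#'
#' Orders fits of the same time course by goodness of fit: higher R2 first,
#' ties broken by lower RMS. The per-criterion winners are reported
#' separately; the combined verdict is the top of the ranking, with a tie
#' flag when the leaders are indistinguishable on both criteria.
#'
#' @param fits list of `kinetic_fit` objects for the same time course.
#' @return A `model_comparison`: ranking table, per-criterion winners,
#'   combined `verdict` (model name) and `tie` flag.
#' @examples
#' tc <- gen_timecourse(b = 0.441, k = 2.46e-3, sigma = 0.01, seed = 1)
#' compare_models(list(fit_unsteady_diffusion(tc), fit_ponomarev(tc)))
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, inherits, TRUE, "kinetic_fit")))
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    r2 = vapply(fits, `[[`, 0, "r2"),
    rms_percent = vapply(fits, `[[`, 0, "rms_percent"))
  ord <- order(-tab$r2, tab$rms_percent)
  ranked <- tab[ord, ]
  ranked$rank <- seq_len(nrow(ranked))
  tie <- nrow(ranked) > 1 &&
    ranked$r2[1] == ranked$r2[2] &&
    ranked$rms_percent[1] == ranked$rms_percent[2]
  structure(
    list(ranking = ranked,
         best_r2 = tab$model[which.max(tab$r2)],
         best_rms = tab$model[which.min(tab$rms_percent)],
         verdict = ranked$model[1],
         tie = tie),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Kinetic model comparison\n")
  print(x$ranking, row.names = FALSE)
  cat(sprintf("Best R2: %s; best RMS: %s; verdict: %s%s\n",
              x$best_r2, x$best_rms, x$verdict,
              if (x$tie) " (tie)" else ""))
  invisible(x)
}
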