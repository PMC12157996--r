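# 2^k full factorial design: coded first-order polynomial with all
# interactions, effect ANOVA, percentage contributions, reduction, prediction.

term_names <- function(k) {
  sets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(k, m, simplify = FALSE)), recursive = FALSE)
  c("b0", vapply(sets, function(s) paste0("x", s, collapse = ""), ""))
}

# Full coded model matrix (intercept + all interaction products) for a matrix
# of coded levels; columns named b0, x1, ..., x1x2...xk.
coded_model_matrix <- function(X) {
  k <- ncol(X)
  sets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(k, m, simplify = FALSE)), recursive = FALSE)
  prods <- vapply(sets, function(s)
    apply(X[, s, drop = FALSE], 1, prod), numeric(nrow(X)))
  if (!is.matrix(prods)) prods <- matrix(prods, nrow = nrow(X))
  M <- cbind(1, prods)
  colnames(M) <- term_names(k)
  M
}

#' Full factorial dataset
#'
#' Validates a complete two-level (2^k) factorial experiment. Each row of
#' `design` is one observation: coded factor levels in \{-1, +1\} plus the
#' measured response; replicates appear as repeated level combinations. Every
#' one of the 2^k coded combinations must be present the same number of times.
#'
#' @param design data frame with one column per coded factor (values -1/+1)
#'   and a numeric response column.
#' @param response name of the response column (default `"response"`).
#' @param factors character vector naming the coded factor columns; defaults
#'   to every column of `design` except the response.
#'
#' @return An object of class `factorial_dataset` with the per-run means,
#'   the raw observations, and the design dimensions.
#' @examples
#' d <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1))
#' d$response <- 10 + 2 * d$x1 - d$x2
#' factorial_dataset(d)
#' @export
factorial_dataset <- function(design, response = "response", factors = NULL) {
  stopifnot(is.data.frame(design))
  if (!response %in% names(design))
    stop_ec("response column `%s` not found", response, class = "schema_error")
  factors <- factors %||% setdiff(names(design), response)
  k <- length(factors)
  if (k < 1L) stop_ec("no factor columns", class = "design_error")
  X <- as.matrix(design[factors])
  if (!all(X %in% c(-1, 1)))
    stop_ec("coded levels must be -1 or +1", class = "design_error")
  y <- design[[response]]
  if (!is.numeric(y) || !all(is.finite(y)))
    stop_ec("responses must be finite numbers", class = "value_error")

  key <- apply(X, 1, paste, collapse = ",")
  full <- expand.grid(rep(list(c(-1, 1)), k))
  full_key <- apply(as.matrix(full), 1, paste, collapse = ",")
  missing <- setdiff(full_key, key)
  if (length(missing))
    stop_ec("incomplete 2^%d design; missing level combination(s): %s",
            k, paste(missing, collapse = "; "), class = "design_error")
  counts <- table(key)
  if (length(unique(as.integer(counts))) != 1L)
    stop_ec("unbalanced design: replicate counts differ across runs (%s)",
            paste(range(counts), collapse = "-"), class = "design_error")

  runs <- full
  names(runs) <- factors
  run_mean <- vapply(full_key, function(kk) mean(y[key == kk]), 0)
  runs$mean_response <- unname(run_mean)

  structure(
    list(runs = runs, factors = factors, k = k,
         n_runs = 2L^k, replicates = as.integer(counts[[1L]]),
         n_obs = nrow(design),
         observations = data.frame(design[factors], response = y,
                                   .run = match(key, full_key))),
    class = "factorial_dataset")
}

#' @export
print.factorial_dataset <- function(x, ...) {
  cat(sprintf("2^%d full factorial dataset: %d runs x %d replicate(s)\n",
              x$k, x$n_runs, x$replicates))
  print(x$runs)
  invisible(x)
}

#' Fit the coded first-order factorial polynomial
#'
#' Estimates the intercept and all main-effect and interaction coefficients
#' of the coded model
#' \deqn{y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j + \dots}
#' by orthogonal contrasts on the run means: `b0` is the grand mean of run
#' means and each effect coefficient is the mean of (coded product times run
#' mean). On a complete two-level design this is identical to least squares.
#'
#' @param data a [factorial_dataset()].
#' @return A `factorial_fit` with the named coefficient vector (`b0`, `x1`,
#'   ..., `x1x2...`), the design dimensions and (until [anova_factorial()] is
#'   called) empty ANOVA/diagnostic slots.
#' @examples
#' fit <- fit_factorial(erica_factorial("hep2c"))
#' coef(fit)[["b0"]]
#' @export
fit_factorial <- function(data) {
  stopifnot(inherits(data, "factorial_dataset"))
  M <- coded_model_matrix(as.matrix(data$runs[data$factors]))
  b <- drop(crossprod(M, data$runs$mean_response)) / data$n_runs
  factorial_fit(setNames(b, colnames(M)), data = data)
}

#' Assemble a factorial fit from known coefficients
#'
#' Builds a `factorial_fit` directly from a named coefficient vector, e.g.
#' published regression coefficients, so that the downstream ANOVA,
#' percentage-contribution, reduction and prediction steps can be applied to
#' reported models as well as to freshly fitted ones.
#'
#' @param coefficients named numeric vector with an intercept `b0` and effect
#'   terms named `x1`, `x2`, `x1x2`, ... covering a full 2^k term set.
#' @param data optional [factorial_dataset()] the coefficients belong to.
#' @return A `factorial_fit`.
#' @examples
#' factorial_fit(erica_effects("hep2c"))
#' @export
factorial_fit <- function(coefficients, data = NULL) {
  k <- round(log2(length(coefficients)))
  expected <- term_names(k)
  if (length(coefficients) != 2^k || !setequal(names(coefficients), expected))
    stop_ec("coefficients must be a full 2^k term set (b0, x1, ..., %s)",
            expected[length(expected)], class = "value_error")
  structure(
    list(coefficients = coefficients[expected], k = k,
         n_runs = 2L^k, data = data,
         anova = NULL, pc_percent = NULL,
         r2 = NA_real_, r2_adj = NA_real_, cv_percent = NA_real_,
         retained_terms = NULL, alpha = NA_real_),
    class = "factorial_fit")
}

#' @export
coef.factorial_fit <- function(object, ...) object$coefficients

#' @export
print.factorial_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Coded 2^%d factorial polynomial\n", x$k))
  print(round(x$coefficients, digits))
  if (!is.null(x$pc_percent)) {
    cat("Percentage contributions (%):\n")
    print(round(x$pc_percent, 2))
  }
  if (!is.null(x$anova)) {
    cat("ANOVA:\n")
    print(x$anova, digits = digits)
    cat(sprintf("R2 = %.4f; R2adj = %.4f; CV = %.2f%%\n",
                x$r2, x$r2_adj, x$cv_percent))
  }
  if (!is.null(x$retained_terms))
    cat("Retained terms (alpha =", x$alpha, "):",
        paste(x$retained_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Effect ANOVA of a factorial fit
#'
#' Decomposes the response variation into single-degree-of-freedom effect
#' sums of squares plus a pure replicate error. Under the default
#' `paper_runs` convention `SS(term) = n_runs * b^2`; under
#' `total_observations` it is `N_obs * b^2`. The error SS is the pooled
#' within-run replicate SS with `N_obs - n_runs` degrees of freedom. When the
#' design carries no replicates (one observation per run) an externally
#' determined error SS and df must be supplied via `error_ss`/`error_df`,
#' which also override replicate error when given. F statistics are
#' `MS(term)/MS(error)` and p-values the upper tail of F(1, df_error).
#'
#' @param fit a `factorial_fit`.
#' @param data the [factorial_dataset()]; defaults to the one stored in `fit`.
#' @param config a [run_config()]; supplies `ss_convention`.
#' @param error_ss,error_df optional external pure-error sum of squares and
#'   degrees of freedom.
#' @return The fit with its `anova` table and diagnostics filled in.
#' @examples
#' fit <- fit_factorial(erica_factorial("hep2c"))
#' err <- erica_pure_error("hep2c")
#' anova_factorial(fit, error_ss = err$ss, error_df = err$df)
#' @export
anova_factorial <- function(fit, data = fit$data, config = run_config(),
                            error_ss = NULL, error_df = NULL) {
  stopifnot(inherits(fit, "factorial_fit"))
  n_runs <- fit$n_runs

  if (is.null(error_ss)) {
    if (is.null(data))
      stop_ec("no data and no external error SS supplied", class = "value_error")
    if (data$replicates < 2L)
      stop_ec(paste("no pure-error degrees of freedom (single replicate);",
                    "supply external `error_ss` and `error_df`"),
              class = "design_error")
    obs <- data$observations
    err_ss <- sum((obs$response - data$runs$mean_response[obs$.run])^2)
    err_df <- data$n_obs - n_runs
    n_obs <- data$n_obs
  } else {
    if (is.null(error_df))
      stop_ec("`error_df` must accompany `error_ss`", class = "value_error")
    check_number(error_ss, "error_ss", lower = 0)
    check_number(error_df, "error_df", lower = 1)
    err_ss <- error_ss
    err_df <- error_df
    # external error df implies the replicate observations behind it
    n_obs <- n_runs + error_df
  }

  b <- fit$coefficients[-1L]
  n_ss <- switch(config$ss_convention,
                 paper_runs = n_runs,
                 total_observations = n_obs)
  ss <- n_ss * b^2
  ms_err <- err_ss / err_df
  if (ms_err == 0) {
    warning("zero pure-error mean square; F statistics are infinite")
    f <- ifelse(ss > 0, Inf, NaN)
    p <- ifelse(ss > 0, 0, NaN)
  } else {
    f <- ss / ms_err
    p <- pf(f, 1, err_df, lower.tail = FALSE)
  }

  total_ss <- sum(ss) + err_ss
  total_df <- n_obs - 1
  fit$anova <- data.frame(
    term = c(names(b), "error", "total"),
    SS = c(ss, err_ss, total_ss),
    df = c(rep(1, length(b)), err_df, total_df),
    MS = c(ss, ms_err, total_ss / total_df),
    F = c(f, NA, NA),
    p = c(p, NA, NA),
    row.names = NULL)

  fit$r2 <- 1 - err_ss / total_ss
  fit$r2_adj <- 1 - (err_ss / err_df) / (total_ss / total_df)
  grand <- fit$coefficients[["b0"]]
  if (grand == 0)
    stop_ec("grand mean is zero; CV undefined", class = "value_error")
  fit$cv_percent <- 100 * sqrt(ms_err) / grand
  fit$pc_percent <- percentage_contribution(fit)
  fit
}

#' Percentage contribution of each effect
#'
#' Shares out 100% among the non-intercept terms in proportion to the
#' absolute value of their coefficients:
#' `PC(term) = 100 |b_term| / sum |b|`. If every effect coefficient is zero
#' the contribution is undefined and a uniform split is returned with a
#' warning.
#'
#' @param fit a `factorial_fit`.
#' @return Named numeric vector of percentages summing to 100.
#' @examples
#' percentage_contribution(factorial_fit(erica_effects("hep2c")))
#' @export
percentage_contribution <- function(fit) {
  stopifnot(inherits(fit, "factorial_fit"))
  b <- abs(fit$coefficients[-1L])
  if (sum(b) == 0) {
    warning("all effect coefficients are zero; returning uniform contributions")
    return(setNames(rep(100 / length(b), length(b)), names(b)))
  }
  100 * b / sum(b)
}

#' Drop insignificant terms
#'
#' Retains the intercept plus every effect whose ANOVA p-value is below
#' `alpha`. On an orthogonal two-level design the remaining coefficients are
#' unchanged by dropping terms, so no refit is performed.
#'
#' @param fit a `factorial_fit` with its ANOVA computed.
#' @param alpha significance level (default 0.05).
#' @return The fit with `retained_terms` set.
#' @examples
#' fit <- anova_factorial(factorial_fit(erica_effects("hep2c")),
#'                        error_ss = 0.00016, error_df = 8)
#' reduce_model(fit)$retained_terms
#' @export
reduce_model <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "factorial_fit"))
  if (is.null(fit$anova))
    stop_ec("run `anova_factorial()` before reducing the model",
            class = "value_error")
  check_number(alpha, "alpha", 0, 1)
  tab <- fit$anova[!fit$anova$term %in% c("error", "total"), ]
  fit$retained_terms <- c("b0", tab$term[!is.na(tab$p) & tab$p < alpha])
  fit$alpha <- alpha
  fit
}

#' Predict the response at a coded point
#'
#' Evaluates the (reduced, if [reduce_model()] has been applied) coded
#' polynomial at a point of the factor space. Points outside the coded cube
#' \[-1, 1\]^k are extrapolations and trigger a warning but are still
#' evaluated.
#'
#' @param fit a `factorial_fit`.
#' @param coded_point numeric vector of length k with the coded factor levels.
#' @return Predicted response (single number).
#' @examples
#' fit <- reduce_model(anova_factorial(factorial_fit(erica_effects("hep2c")),
#'                                     error_ss = 0.00016, error_df = 8))
#' predict_yield(fit, c(-1, -1, -1))
#' @export
predict_yield <- function(fit, coded_point) {
  stopifnot(inherits(fit, "factorial_fit"))
  if (length(coded_point) != fit$k)
    stop_ec("coded point must have %d coordinates", fit$k, class = "value_error")
  if (any(abs(coded_point) > 1))
    warning("coded point outside [-1, 1]^k: extrapolating")
  M <- coded_model_matrix(matrix(as.numeric(coded_point), nrow = 1))
  keep <- fit$retained_terms %||% names(fit$coefficients)
  sum(fit$coefficients[keep] * M[1, keep])
}

#' Model-quality diagnostics
#'
#' Returns the coefficient of determination, its adjusted version and the
#' coefficient of variation of a factorial fit:
#' `R2 = 1 - SS_error/SS_total`,
#' `R2adj = 1 - MS_error/(SS_total/df_total)`,
#' `CV% = 100 sqrt(MS_error)/grand mean`.
#'
#' @param fit a `factorial_fit` with its ANOVA computed.
#' @return Named list with `r2`, `r2_adj` and `cv_percent`.
#' @examples
#' fit <- anova_factorial(fit_factorial(erica_factorial("hep2c")),
#'                        error_ss = 0.00016, error_df = 8)
#' fit_diagnostics(fit)
#' @export
fit_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "factorial_fit"))
  if (is.null(fit$anova))
    stop_ec("run `anova_factorial()` first", class = "value_error")
  list(r2 = fit$r2, r2_adj = fit$r2_adj, cv_percent = fit$cv_percent)
}

#' @export
as.data.frame.factorial_fit <- function(x, ...) {
  pc <- x$pc_percent %||% percentage_contribution(x)
  data.frame(term = names(x$coefficients),
             coefficient = unname(x$coefficients),
             PC_percent = c(NA, unname(pc)),
             row.names = NULL)
}
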