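random_design <- function(seed, replicates = 2, sigma = 0.02) {
  set.seed(seed)
  runs <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1))
  obs <- runs[rep(1:8, each = replicates), ]
  obs$response <- round(runif(8)[rep(1:8, each = replicates)] +
                          rnorm(nrow(obs), 0, sigma), 8)
  rownames(obs) <- NULL
  obs
}

test_that("a constant response yields the constant intercept and zero effects", {
  d <- random_design(1)
  d$response <- 0.37
  fit <- fit_factorial(factorial_dataset(d))
  expect_equal(coef(fit)[["b0"]], 0.37)
  expect_equal(unname(coef(fit)[-1]), rep(0, 7))
})

test_that("contrast coefficients equal normal-equation least squares", {
  for (seed in 1:5) {
    obs <- random_design(seed)
    fit <- fit_factorial(factorial_dataset(obs))
    oracle <- oracle_factorial_coef(obs)
    expect_equal(coef(fit)[names(oracle)], oracle, tolerance = 1e-10)
  }
})

test_that("coefficients are orthogonal: unchanged when other terms are dropped", {
  obs <- random_design(11)
  full <- coef(fit_factorial(factorial_dataset(obs)))
  # refit progressively smaller sub-models by least squares
  sub_models <- list(~ x1 + x2 + x3, ~ x1 * x3, ~ x1)
  for (fm in sub_models) {
    X <- stats::model.matrix(fm, data = obs)
    beta <- drop(solve(t(X) %*% X, t(X) %*% obs$response))
    names(beta) <- gsub(":", "", names(beta))
    names(beta)[1] <- "b0"
    expect_equal(full[names(beta)], beta, tolerance = 1e-10)
  }
})

test_that("effect SS match the contrast-sum oracle under both conventions", {
  obs <- random_design(3)
  data <- factorial_dataset(obs)
  fit <- fit_factorial(data)
  oracle <- oracle_contrast_ss(obs)  # = N_obs * b^2 on a balanced design

  tot <- anova_factorial(fit, data,
                         config = run_config(ss_convention = "total_observations"))
  ss_tot <- setNames(tot$anova$SS, tot$anova$term)[names(oracle)]
  expect_equal(ss_tot, oracle, tolerance = 1e-10)

  runs <- anova_factorial(fit, data)  # paper_runs: SS = n_runs * b^2
  ss_runs <- setNames(runs$anova$SS, runs$anova$term)[names(oracle)]
  expect_equal(ss_runs, oracle * 8 / nrow(obs), tolerance = 1e-10)
})

test_that("ANOVA pools replicate error and decomposes the total SS", {
  obs <- random_design(4)
  data <- factorial_dataset(obs)
  fit <- anova_factorial(fit_factorial(data), data,
                         config = run_config(ss_convention = "total_observations"))
  tab <- fit$anova
  err <- tab[tab$term == "error", ]
  expect_equal(err$df, nrow(obs) - 8)
  expect_equal(tab$df[tab$term == "total"], nrow(obs) - 1)
  expect_equal(tab$SS[tab$term == "total"],
               sum(tab$SS[!tab$term %in% "total"]), tolerance = 1e-12)
  # under the observation convention the decomposition is the classical one
  expect_equal(tab$SS[tab$term == "total"],
               sum((obs$response - mean(obs$response))^2), tolerance = 1e-10)
})

test_that("single-replicate designs demand an external error term", {
  d <- random_design(5, replicates = 1, sigma = 0)
  data <- factorial_dataset(d)
  fit <- fit_factorial(data)
  expect_error(anova_factorial(fit, data), "pure-error",
               class = "design_error")
  filled <- anova_factorial(fit, data, error_ss = 0.0002, error_df = 8)
  expect_equal(filled$anova$df[filled$anova$term == "total"], 15)
})

test_that("zero replicate noise flags infinite F statistics", {
  d <- random_design(6, replicates = 2, sigma = 0)
  data <- factorial_dataset(d)
  expect_warning(fit <- anova_factorial(fit_factorial(data), data),
                 "infinite")
  expect_true(all(is.infinite(fit$anova$F[1:7]) | is.nan(fit$anova$F[1:7])))
})

test_that("percentage contributions are normalized shares of |coefficient|", {
  fit <- factorial_fit(erica_effects("hep2c"))
  pc <- percentage_contribution(fit)
  expect_equal(sum(pc), 100)
  expect_equal(pc[["x3"]], 67.67, tolerance = 1e-2)

  single <- factorial_fit(c(b0 = 1, x1 = 0, x2 = 0.5, x3 = 0, x1x2 = 0,
                            x1x3 = 0, x2x3 = 0, x1x2x3 = 0))
  expect_equal(percentage_contribution(single)[["x2"]], 100)

  null_fit <- factorial_fit(c(b0 = 1, x1 = 0, x2 = 0, x3 = 0, x1x2 = 0,
                              x1x3 = 0, x2x3 = 0, x1x2x3 = 0))
  expect_warning(pc0 <- percentage_contribution(null_fit), "uniform")
  expect_equal(unname(pc0), rep(100 / 7, 7))
})

test_that("model reduction keeps the intercept plus sub-alpha terms", {
  err <- erica_pure_error("hep2c")
  fit <- anova_factorial(factorial_fit(erica_effects("hep2c")),
                         error_ss = err$ss, error_df = err$df)
  red <- reduce_model(fit, alpha = 0.05)
  expect_setequal(red$retained_terms,
                  c("b0", "x1", "x2", "x3", "x1x3", "x2x3", "x1x2x3"))

  all_in <- reduce_model(fit, alpha = 1)
  expect_length(all_in$retained_terms, 8)

  expect_error(reduce_model(factorial_fit(erica_effects("rd"))),
               "anova", class = "value_error")
})

test_that("the saturated model reproduces every run mean at the corners", {
  obs <- random_design(7)
  data <- factorial_dataset(obs)
  fit <- fit_factorial(data)
  for (i in 1:8) {
    corner <- as.numeric(data$runs[i, c("x1", "x2", "x3")])
    expect_equal(predict_yield(fit, corner), data$runs$mean_response[i],
                 tolerance = 1e-12)
  }
  # centre of the cube is the intercept
  expect_equal(predict_yield(fit, c(0, 0, 0)), coef(fit)[["b0"]])
  expect_warning(predict_yield(fit, c(2, 0, 0)), "extrapolating")
  expect_error(predict_yield(fit, c(1, 1)), class = "value_error")
})

test_that("diagnostics follow their defining formulas", {
  obs <- random_design(8)
  data <- factorial_dataset(obs)
  fit <- anova_factorial(fit_factorial(data), data)
  d <- fit_diagnostics(fit)
  tab <- fit$anova
  ss_err <- tab$SS[tab$term == "error"]
  ss_tot <- tab$SS[tab$term == "total"]
  expect_equal(d$r2, 1 - ss_err / ss_tot)
  expect_lte(d$r2_adj, d$r2)
  expect_true(d$r2 >= 0 && d$r2 <= 1)
  expect_equal(d$cv_percent,
               100 * sqrt(ss_err / 8) / mean(obs$response), tolerance = 1e-10)

  # zero-error design: perfect fit
  d0 <- random_design(9, replicates = 2, sigma = 0)
  dat0 <- factorial_dataset(d0)
  suppressWarnings(fit0 <- anova_factorial(fit_factorial(dat0), dat0))
  expect_equal(fit0$r2, 1)
  expect_equal(fit0$cv_percent, 0)
})

test_that("invalid designs are rejected with informative errors", {
  obs <- random_design(10)
  expect_error(factorial_dataset(obs[-c(1, 2), ]), "missing level",
               class = "design_error")
  expect_error(factorial_dataset(obs[-1, ]), "unbalanced",
               class = "design_error")
  bad <- obs
  bad$x1[1:2] <- 0.5
  expect_error(factorial_dataset(bad), "-1 or \\+1", class = "design_error")
  bad2 <- obs
  bad2$response[1] <- NA
  expect_error(factorial_dataset(bad2), class = "value_error")
  expect_error(factorial_fit(c(b0 = 1, x1 = 0, x2 = 1)),
               class = "value_error")
  expect_error(factorial_fit(c(b0 = 1, x1 = 0, x3 = 1, x1x3 = 0)),
               class = "value_error")
})
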