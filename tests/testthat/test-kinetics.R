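test_that("both fitters recover generating parameters exactly on noiseless data", {
  times <- c(10, 15, 20, 30, 40, 60, 80)
  for (b in c(0, 0.25, 0.6, 0.9)) {
    for (k in c(1e-4, 2.46e-3, 1e-2, 1e-1)) {
      # construct the exact model curve (the generator would clip q > 0.999)
      tc <- time_course(times, 1 - (1 - b) * exp(-k * times))
      fd <- fit_unsteady_diffusion(tc)
      expect_equal(fd$washing_coefficient, b, tolerance = 1e-9)
      expect_equal(fd$slow_rate, k, tolerance = 1e-9)
    }
    # Ponomarev on its own generating model (short times: cap inactive)
    tp <- gen_timecourse(b = b, k = 1e-3, model = "ponomarev",
                         times = c(5, 10, 20, 40))
    fp <- fit_ponomarev(tp)
    expect_equal(fp$washing_coefficient, b, tolerance = 1e-9)
    expect_equal(fp$slow_rate, 1e-3, tolerance = 1e-9)
  }
})

test_that("rate constants scale with the time unit, washing does not", {
  tc_min <- gen_timecourse(b = 0.441, k = 2.46e-3, sigma = 0.01, seed = 21)
  tc_sec <- time_course(tc_min$time * 60, tc_min$yield)
  f_min <- fit_unsteady_diffusion(tc_min)
  f_sec <- fit_unsteady_diffusion(tc_sec)
  expect_equal(f_min$slow_rate, f_sec$slow_rate * 60, tolerance = 1e-12)
  expect_equal(f_min$washing_coefficient, f_sec$washing_coefficient,
               tolerance = 1e-12)
})

test_that("degenerate curves are flagged, not crashed on", {
  # washing-only limit: constant q = b
  tc <- time_course(c(10, 20, 40), rep(0.4, 3))
  w <- capture_warnings(fit <- fit_unsteady_diffusion(tc))
  expect_match(w, "flagged", all = FALSE)
  expect_match(w, "undefined", all = FALSE)
  expect_equal(fit$slow_rate, 0, tolerance = 1e-12)

  # q >= 1 points are dropped before taking logs
  tc2 <- suppressWarnings(time_course(c(10, 20, 40, 60), c(0.5, 0.6, 1, 0.7)))
  expect_warning(fit2 <- fit_unsteady_diffusion(tc2), "dropped")
  expect_equal(fit2$n_used, 3)
  tc3 <- suppressWarnings(time_course(c(10, 20, 40), c(0.5, 1, 1)))
  expect_error(suppressWarnings(fit_unsteady_diffusion(tc3)),
               class = "fit_error")
})

test_that("the Ponomarev fit matches the closed-form regression oracle", {
  set.seed(31)
  for (i in 1:5) {
    q <- pmin(pmax(0.4 + 2e-3 * c(10, 15, 20, 30, 40, 60, 80) +
                     rnorm(7, 0, 0.01), 0), 0.999)
    tc <- suppressWarnings(time_course(c(10, 15, 20, 30, 40, 60, 80), q))
    fit <- fit_ponomarev(tc)
    oracle <- oracle_simple_regression(tc$time, tc$yield)
    expect_equal(fit$washing_coefficient, oracle$intercept, tolerance = 1e-12)
    expect_equal(fit$slow_rate, oracle$slope, tolerance = 1e-12)
  }
  # a two-point window gives the exact interpolating line
  tc2 <- time_course(c(10, 20, 50), c(0.40, 0.45, 0.50))
  fit2 <- fit_ponomarev(tc2, t_min = 15)
  expect_equal(fit2$washing_coefficient + fit2$slow_rate * c(20, 50),
               c(0.45, 0.50), tolerance = 1e-12)
})

test_that("goodness of fit follows its definition on the original scale", {
  tc <- gen_timecourse(b = 0.3, k = 5e-3, sigma = 0.01, seed = 8)
  fit <- fit_unsteady_diffusion(tc)
  qhat <- predict(fit)
  g <- goodness_of_fit(tc, fit)
  expect_equal(g$r2,
               1 - sum((tc$yield - qhat)^2) / sum((tc$yield - mean(tc$yield))^2))
  expect_equal(g$rms_percent,
               100 * sqrt(mean(((qhat - tc$yield) / tc$yield)^2)))

  # a perfect fit has r2 = 1, rms = 0
  tc0 <- gen_timecourse(b = 0.3, k = 5e-3)
  g0 <- goodness_of_fit(tc0, fit_unsteady_diffusion(tc0))
  expect_equal(g0$r2, 1, tolerance = 1e-12)
  expect_equal(g0$rms_percent, 0, tolerance = 1e-6)

  # constant data: r2 undefined
  tcc <- time_course(c(10, 20, 40), rep(0.4, 3))
  fitc <- suppressWarnings(fit_unsteady_diffusion(tcc))
  expect_warning(gc <- goodness_of_fit(tcc, fitc), "undefined")
  expect_true(is.nan(gc$r2))

  # zero-yield points are excluded from the relative RMS
  tcz <- time_course(c(5, 10, 20, 40), c(0, 0.2, 0.3, 0.4))
  fitz <- suppressWarnings(fit_ponomarev(tcz))
  expect_warning(goodness_of_fit(tcz, fitz), "excluded")
})

test_that("model ranking prefers higher R2, then lower RMS, and flags ties", {
  tc <- gen_timecourse(b = 0.441, k = 2.46e-3, sigma = 0.01, seed = 5)
  fd <- fit_unsteady_diffusion(tc)
  fp <- fit_ponomarev(tc)
  cmp <- compare_models(list(fd, fp))
  expect_equal(cmp$verdict, cmp$ranking$model[1])
  expect_equal(cmp$ranking$r2, sort(cmp$ranking$r2, decreasing = TRUE))

  # dominance: higher r2 wins outright
  f1 <- fd; f1$r2 <- 0.95; f1$rms_percent <- 5
  f2 <- fp; f2$r2 <- 0.90; f2$rms_percent <- 4
  cmp2 <- compare_models(list(f2, f1))
  expect_equal(cmp2$verdict, f1$model)
  expect_equal(cmp2$best_rms, f2$model)

  # exact tie on both criteria is stable and flagged
  f3 <- f1; f3$model <- "ponomarev"
  cmp3 <- compare_models(list(f1, f3))
  expect_true(cmp3$tie)
  expect_equal(cmp3$ranking$model, c("unsteady_diffusion", "ponomarev"))
})

test_that("hotter extractions fit faster slow-stage rates (positive Ea)", {
  rs <- gen_arrhenius(Ea = 13.89, A = 0.33, temperature = c(30, 40, 50))
  k_fit <- vapply(rs$k, function(k) {
    fit_unsteady_diffusion(gen_timecourse(b = 0.35, k = k))$slow_rate
  }, 0)
  expect_true(all(diff(k_fit) > 0))
})

test_that("time courses validate their inputs", {
  expect_error(time_course(c(10, 20), c(0.1, 0.2)), class = "value_error")
  expect_error(time_course(c(10, 10, 20), c(0.1, 0.2, 0.3)),
               class = "value_error")
  expect_error(time_course(c(10, 20, 30), c(0.1, 0.2, 1.3)),
               class = "value_error")
  expect_warning(time_course(c(10, 20, 30), c(0.5, 0.4, 0.5)), "decreases")
})
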