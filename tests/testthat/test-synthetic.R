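test_that("generators are deterministic per seed and spare the RNG stream", {
  a <- gen_factorial(erica_effects("hep2c"), sigma = 0.005, seed = 11)
  b <- gen_factorial(erica_effects("hep2c"), sigma = 0.005, seed = 11)
  expect_identical(a, b)
  c <- gen_factorial(erica_effects("hep2c"), sigma = 0.005, seed = 12)
  expect_false(identical(a, c))

  set.seed(123)
  before <- .Random.seed
  invisible(gen_timecourse(b = 0.4, k = 2e-3, sigma = 0.01, seed = 1))
  invisible(gen_arrhenius(Ea = 10, A = 0.3, sigma_ln = 0.1, seed = 2))
  invisible(gen_panel(c(a = 10, b = 20), seed = 3))
  expect_identical(.Random.seed, before)

  # and byte-identical CSV output downstream
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  for (f in c(f1, f2)) {
    tc <- gen_timecourse(b = 0.441, k = 2.46e-3, sigma = 0.01, seed = 9)
    write_extraction_table(
      data.frame(ethanol_pct = 30, temp_C = 30, time_min = tc$time,
                 response = tc$yield), f, "timecourse")
  }
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noiseless factorial data reproduce the generating polynomial", {
  beta <- erica_effects("hep2c")
  d <- gen_factorial(beta, replicates = 2, sigma = 0)
  fit <- fit_factorial(d)
  expect_equal(coef(fit), beta, tolerance = 1e-12)
})

test_that("factorial coefficient estimates are unbiased under replicate noise", {
  beta <- erica_effects("hep2c")
  sigma <- 0.005
  set.seed(500)
  est <- vapply(1:500, function(i) {
    coef(fit_factorial(gen_factorial(beta, replicates = 2, sigma = sigma)))
  }, beta)
  bias <- rowMeans(est) - beta
  # one dataset estimates each coefficient with sd sigma/sqrt(16); averaging
  # 500 seeds shrinks the Monte-Carlo error by sqrt(500)
  expect_true(all(abs(bias) < 3 * sigma / sqrt(16) / sqrt(500)))
})

test_that("synthetic time courses hit their boundary values", {
  # t = 0 exposes the washing intercept
  tc <- gen_timecourse(b = 0.37, k = 2e-3, times = c(0, 10, 20))
  expect_equal(tc$yield[1], 0.37)
  tp <- gen_timecourse(b = 0.37, k = 2e-3, model = "ponomarev",
                       times = c(0, 10, 20))
  expect_equal(tp$yield[1], 0.37)
  # saturation: kt >> 1 approaches full recovery within the clip
  tl <- gen_timecourse(b = 0.3, k = 0.5, times = c(10, 50, 100, 500))
  expect_equal(tl$yield[4], 0.999)
  # the Ponomarev line is capped at complete extraction
  tpc <- gen_timecourse(b = 0.9, k = 0.01, model = "ponomarev",
                        times = c(1, 10, 100))
  expect_equal(tpc$yield[3], 0.999)
})

test_that("flat Arrhenius spec gives constant rates equal to A", {
  rs <- gen_arrhenius(Ea = 0, A = 2.5e-3)
  expect_equal(rs$k, rep(2.5e-3, 3))
})

test_that("the Hill generator places 50% inhibition at the IC50", {
  curve <- gen_dose_response(ic50 = 14.29, hill = 1,
                             concentration = c(5, 14.29, 40))
  expect_equal(curve$inhibition[2], 50)
})

test_that("panel loading controls the induced cross-assay correlation", {
  # rank-one panel: all pairwise correlations are 1
  p1 <- gen_panel(c(a = 10, b = 20, c = 40), loading = 1, sigma = 0, seed = 5)
  r1 <- pearson_matrix(p1)
  expect_equal(unname(r1[upper.tri(r1)]), rep(1, 3), tolerance = 1e-12)

  # zero loading: independent columns, correlations centred on zero
  rs <- unlist(lapply(1:200, function(s) {
    p <- gen_panel(c(a = 10, b = 20, c = 40), loading = 0, sigma = 0.3,
                   seed = s)
    r <- pearson_matrix(p)
    r[upper.tri(r)]
  }))
  expect_lt(abs(stats::median(rs)), 0.2)
})

test_that("noise channels match their nominal mean and variance", {
  n <- 1e4
  beta <- c(b0 = 0.5, x1 = 0, x2 = 0, x3 = 0, x1x2 = 0, x1x3 = 0,
            x2x3 = 0, x1x2x3 = 0)
  sigma <- 0.01
  d <- gen_factorial(beta, replicates = n / 8, sigma = sigma, seed = 77)
  res <- d$observations$response - 0.5
  expect_lt(abs(mean(res)), 3 * sigma / sqrt(n))
  # var of the sample variance of a normal: 2 sigma^4 / (n - 1)
  expect_lt(abs(var(res) - sigma^2), 3 * sqrt(2 * sigma^4 / (n - 1)))

  # lognormal rate noise: log k centred on the Arrhenius line
  rs <- gen_arrhenius(Ea = 10, A = 0.33, temperature = rep(c(30, 40, 50),
                                                           length.out = n),
                      sigma_ln = 0.05, seed = 78)
  mu <- log(0.33) - 1000 * 10 / (r_gas * rs$T_K)
  z <- log(rs$k) - mu
  expect_lt(abs(mean(z)), 3 * 0.05 / sqrt(n))
  expect_lt(abs(var(z) - 0.05^2), 3 * sqrt(2 * 0.05^4 / (n - 1)))
})

test_that("generator arguments are validated", {
  beta <- erica_effects("rd")
  expect_error(gen_factorial(beta[-2]), class = "value_error")
  expect_error(gen_factorial(beta, sigma = -1), class = "value_error")
  expect_error(gen_timecourse(b = 1, k = 1e-3), class = "value_error")
  expect_error(gen_timecourse(b = 0.5, k = 0), class = "value_error")
  expect_error(gen_arrhenius(Ea = -1, A = 1), class = "value_error")
  expect_error(gen_dose_response(ic50 = 0), class = "value_error")
  expect_error(gen_panel(c(a = -1)), class = "value_error")
  expect_error(gen_dilution(0), class = "value_error")
})
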