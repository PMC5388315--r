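test_that("traditional fit matches the closed-form normal equations", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    x <- sort(runif(n, 15, 32))
    y <- 0.001 + runif(1, 0.001, 0.01) * x + rnorm(n, sd = 0.002)
    fit <- fit_traditional(data.frame(temperature = x, rate = y))
    oracle <- ols_oracle(x, y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
    # intercepts can cross zero, so scale the comparison by the data
    expect_lt(abs(fit$intercept - oracle$intercept),
              1e-12 * max(1, abs(oracle$intercept), max(abs(y))))
  }
})

test_that("the whole-immature degree-day line reproduces its frozen values", {
  fit <- fit_traditional(immature_rates(with_descending = FALSE))
  expect_equal(fit$slope, 0.0023261065, tolerance = 1e-7)
  expect_equal(fit$intercept, -0.02387282, tolerance = 1e-6)
  expect_equal(fit$t_min, 10.26299, tolerance = 1e-5)
  expect_equal(fit$k, 429.9029, tolerance = 1e-5)
  expect_equal(fit$se_t_min, 1.575209, tolerance = 1e-5)
  expect_equal(fit$se_k, 43.09567, tolerance = 1e-5)
  expect_equal(fit$r2, 0.9802978, tolerance = 1e-6)
  expect_lt(fit$p_value, 0.01)
})

test_that("a noiseless degree-day line is recovered exactly", {
  temps <- c(20, 24, 28, 30)
  fit <- fit_traditional(data.frame(temperature = temps,
                                    rate = 0.01 * (temps - 15)))
  expect_equal(fit$t_min, 15)
  expect_equal(fit$k, 100)
  expect_equal(fit$r2, 1)
  expect_equal(fit$se_t_min, 0)
  expect_equal(fit$se_k, 0)
  # structural identities
  expect_equal(fit$k * fit$slope, 1)
  expect_equal(fit$intercept + fit$slope * fit$t_min, 0)
})

test_that("Ikemoto-Takai regression matches hand OLS and the egg example", {
  egg <- data.frame(temperature = c(20, 24, 28, 30),
                    duration = c(6.52, 4.76, 3.71, 3.00))
  fit <- fit_ikemoto_takai(egg)
  oracle <- ols_oracle(egg$duration, egg$duration * egg$temperature)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(fit$t_min, 10.98557, tolerance = 1e-5)
  expect_equal(fit$k, 60.2224, tolerance = 1e-4)

  imm <- fit_ikemoto_takai(immature_durations())
  expect_equal(imm$t_min, 11.21094, tolerance = 1e-5)
  expect_equal(imm$k, 402.4791, tolerance = 1e-5)
})

test_that("both linear models agree exactly on noiseless degree-day data", {
  t_min <- 12; k <- 100
  temps <- c(18, 22, 26, 30)
  durs <- k / (temps - t_min)
  trad <- fit_traditional(data.frame(temperature = temps, rate = 1 / durs))
  it <- fit_ikemoto_takai(data.frame(temperature = temps, duration = durs))
  expect_equal(trad$t_min, t_min, tolerance = 1e-9)
  expect_equal(it$t_min, t_min, tolerance = 1e-9)
  expect_equal(trad$k, k, tolerance = 1e-9)
  expect_equal(it$k, k, tolerance = 1e-9)
  expect_equal(it$r2, 1)
})

test_that("threshold and thermal-constant SE formulas evaluate correctly", {
  expect_equal(se_t_min(r_bar = 0.1, s2 = 1e-6, n = 4, b = 0.01, se_b = 1e-4),
               10 * sqrt(2.5e-5 + 1e-4), tolerance = 1e-10)
  expect_equal(se_t_min(0.1, 0, 4, 0.01, 0), 0)
  expect_equal(se_k(b = 0.01, se_b = 1e-4), 1)
  expect_equal(se_k(0.01, 0), 0)
  expect_error(se_t_min(0.1, 1e-6, 4, 0, 1e-4), "zero slope")
  expect_error(se_k(0, 1e-4), "zero slope")
  # nonnegative on random inputs
  set.seed(7)
  for (i in 1:50) {
    v <- se_t_min(runif(1, 0.01, 1), runif(1, 0, 1e-4), sample(3:10, 1),
                  runif(1, 1e-3, 0.1), runif(1, 0, 1e-3))
    expect_gte(v, 0)
  }
})

test_that("duration prediction inverts the degree-day relation", {
  fit <- fit_traditional(data.frame(temperature = c(20, 24, 28, 30),
                                    rate = 0.01 * (c(20, 24, 28, 30) - 12)))
  expect_equal(predict_duration(fit, 22), 100 / (22 - 12))
  expect_error(predict_duration(fit, 12), "undefined")
  imm <- fit_traditional(immature_rates(with_descending = FALSE))
  expect_equal(predict_duration(imm, 30), imm$k / (30 - imm$t_min))
  expect_equal(predict_duration(imm, 30), 21.8, tolerance = 0.01)
})

test_that("degenerate inputs flag rather than crash batch runs", {
  pts <- data.frame(temperature = c(20, 24, 28), rate = c(0.3, 0.2, 0.1))
  fit <- fit_traditional(pts)  # falling rates: negative slope
  expect_equal(fit$flag, "nonpositive_slope")
  expect_true(is.na(fit$t_min))
  expect_error(fit_traditional(pts[1:2, ]), "at least 3 points")
  expect_error(
    fit_traditional(data.frame(temperature = c(20, 20, 20),
                               rate = c(0.1, 0.2, 0.3))),
    "distinct")
})

test_that("weighting by sample size is available but off by default", {
  pts <- immature_rates(with_descending = FALSE)
  pts$weight <- c(112, 107, 80, 106)
  fit_w <- fit_traditional(pts, weights = pts$weight)
  fit_u <- fit_traditional(pts)
  expect_false(isTRUE(all.equal(fit_w$slope, fit_u$slope)))
  oracle <- stats::lm(rate ~ temperature, pts, weights = pts$weight)
  expect_equal(fit_w$slope, unname(coef(oracle)[2]), tolerance = 1e-12)
})
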