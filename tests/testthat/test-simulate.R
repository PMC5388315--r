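test_that("a noiseless continuous cohort reproduces the true durations", {
  cfg <- simulation_config(true_model = "linear_dd",
                           params = c(t_min = 10, k = 400),
                           temperatures = c(20, 24, 28, 30),
                           n_per_temp = 20, cv = 0, census_interval = 0,
                           survival = 1)
  sim <- simulate_cohort(cfg)
  expected <- 400 / (c(20, 24, 28, 30) - 10)
  expect_equal(sim$table$mean_duration_d, expected, tolerance = 1e-12)
  expect_true(all(sim$individuals$survived))
})

test_that("a daily census rounds durations up to the next whole day", {
  # true duration 6.52 d at 20 C: rate = (20 - 10)/65.2
  cfg <- simulation_config(params = c(t_min = 10, k = 65.2),
                           temperatures = 20, n_per_temp = 5, cv = 0,
                           census_interval = 1, survival = 1)
  sim <- simulate_cohort(cfg)
  expect_equal(unique(sim$individuals$duration), 7)
})

test_that("cohorts are bit-identical for the same seed", {
  cfg <- simulation_config(cv = 0.1, n_per_temp = 50, survival = 0.8,
                           seed = 99)
  s1 <- simulate_cohort(cfg); s2 <- simulate_cohort(cfg)
  expect_identical(s1$individuals, s2$individuals)
  cfg$seed <- 100
  s3 <- simulate_cohort(cfg)
  expect_false(identical(s1$individuals, s3$individuals))
})

test_that("derived table equals the sample statistics of survivors", {
  cfg <- simulation_config(cv = 0.1, n_per_temp = 200, survival = 0.7,
                           seed = 5)
  sim <- simulate_cohort(cfg)
  for (tmp in cfg$temperatures) {
    g <- sim$individuals[sim$individuals$temperature == tmp, ]
    row <- sim$table[sim$table$temperature_C == tmp, ]
    d <- g$duration[g$survived]
    expect_equal(row$mean_duration_d, mean(d))
    expect_equal(row$se_d, sd(d) / sqrt(length(d)))
    expect_equal(row$survival, mean(g$survived))
    # sampling check: the mean is close to the truth at this n and cv
    truth <- 400 / (tmp - 10)
    expect_lt(abs(row$mean_duration_d - truth), 2 * truth * 0.1 / sqrt(length(d)))
  }
})

test_that("zero-survival temperatures drop out of the derived table", {
  cfg <- simulation_config(temperatures = c(20, 24, 28),
                           survival = c("20" = 1, "24" = 0, "28" = 1),
                           n_per_temp = 10, cv = 0)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$table$temperature_C, c(20, 28))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_per_temp = 0))
  expect_error(simulation_config(cv = -0.1))
  cfg <- simulation_config(params = c(t_min = 25, k = 400),
                           temperatures = c(20, 30))
  expect_error(simulate_cohort(cfg), "non-positive")
})

test_that("noiseless recovery is exact and noisy recovery is unbiased", {
  cfg0 <- simulation_config(cv = 0, n_per_temp = 20)
  rep0 <- recovery_experiment(cfg0, replicates = 3)
  expect_equal(rep0$bias, rep(0, nrow(rep0)), tolerance = 1e-9)
  expect_equal(rep0$rmse, rep(0, nrow(rep0)), tolerance = 1e-9)

  cfg <- simulation_config(cv = 0.05, n_per_temp = 100)
  rep1 <- recovery_experiment(cfg, replicates = 10)
  tmin_row <- rep1[rep1$model == "traditional" & rep1$quantity == "t_min", ]
  expect_lt(abs(tmin_row$bias), 0.5)
  expect_equal(rep1$n_failed, rep(0L, nrow(rep1)))
  # deterministic given the config seed
  rep2 <- recovery_experiment(cfg, replicates = 10)
  expect_identical(rep1, rep2)
})

test_that("daily-census rounding biases durations upward by under a day", {
  base <- simulation_config(cv = 0.05, n_per_temp = 500, census_interval = 0,
                            seed = 21)
  daily <- base; daily$census_interval <- 1
  s0 <- simulate_cohort(base); s1 <- simulate_cohort(daily)
  delta <- s1$table$mean_duration_d - s0$table$mean_duration_d
  expect_true(all(delta > 0 & delta < 1))
})
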