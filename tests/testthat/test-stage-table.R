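test_that("the bundled rearing table loads with the expected records", {
  tab <- glyphodes_table1()
  expect_s3_class(tab, "stage_table")
  egg20 <- tab[tab$stage == "egg" & tab$temperature_C == 20, ]
  expect_equal(egg20$mean_duration_d, 6.52)
  expect_equal(egg20$n, 112)
  expect_equal(egg20$survival, 0.7038)
  # six temperatures for every composite stage
  for (st in c("egg", "larvae_total", "prepupa", "pupa", "immature_total"))
    expect_length(tab$temperature_C[tab$stage == st], 6)
})

test_that("invalid tables are rejected with row-indexed messages", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("stage,temperature_C,mean_duration_d,se_d,n,survival", tmp)
  expect_error(read_stage_table(tmp), "no observations")

  df <- data.frame(stage = c("egg", "egg"), temperature_C = c(20, 24),
                   mean_duration_d = c(0, 5), se_d = NA, n = 10, survival = 0.5)
  expect_error(stage_table(df), "row 1: mean_duration_d")

  df$mean_duration_d <- c(6, 5); df$temperature_C <- c(20, 20)
  expect_error(stage_table(df), "duplicate \\(stage, temperature\\)")

  expect_error(stage_table(df[, -3]), "missing column")
  expect_error(read_stage_table("does-not-exist.csv"), "file not found")
})

test_that("write/read round-trip is the identity on validated tables", {
  tab <- glyphodes_table1()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_stage_table(tab, tmp)
  back <- read_stage_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
})

test_that("percent survival dialect is converted, never guessed", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("stage,temperature_C,mean_duration_d,se_d,n,survival",
               "egg,20,6.5,0.1,100,70.4"), tmp)
  expect_error(read_stage_table(tmp, survival = "fraction"), "survival")
  tab <- read_stage_table(tmp, survival = "percent")
  expect_equal(tab$survival, 0.704)
})

test_that("rates are reciprocals of mean durations and carry n as weight", {
  tab <- glyphodes_table1()
  egg <- compute_rates(tab, "egg")
  expect_equal(egg$rate[egg$temperature == 20], 1 / 6.52, tolerance = 1e-12)
  expect_equal(egg$weight[egg$temperature == 20], 112)
  imm <- compute_rates(tab, "immature_total")
  expect_equal(imm$rate[imm$temperature %in% c(20, 24, 28, 30)],
               1 / c(46.62, 29.34, 24.47, 22.04))
  expect_error(compute_rates(tab, "adult"), "unknown stage")
  # strictly decreasing in mean duration at fixed temperature
  d <- seq(2, 50, length.out = 20)
  expect_true(all(diff(1 / d) < 0))
})

test_that("range selection drops low-survival and above-peak temperatures", {
  tab <- glyphodes_table1()
  imm <- compute_rates(tab, "immature_total")
  sel <- select_linear_range(imm)
  expect_equal(sel$temperature, c(20, 24, 28, 30))  # 16 (4%) and 32 (past peak) dropped

  # nothing to exclude on a clean rising series
  pts <- data.frame(temperature = c(20, 25, 30), rate = c(0.1, 0.2, 0.3),
                    survival = 1)
  expect_equal(select_linear_range(pts), pts)

  # all survivals too low
  pts$survival <- 0.01
  expect_error(select_linear_range(pts), "fewer than 3 points")

  # subset of input and idempotent
  sel2 <- select_linear_range(sel)
  expect_true(all(sel2$temperature %in% imm$temperature))
  expect_equal(sel2, sel)
})

test_that("an explicit survival map can override the stage's own survival", {
  tab <- glyphodes_table1()
  egg <- compute_rates(tab, "egg")
  # egg survival at 16 C is 66%, but the cohort only reached adulthood for
  # 4% -- the cohort map drops 16 C for the egg stage too
  cohort <- setNames(tab$survival[tab$stage == "immature_total"],
                     tab$temperature_C[tab$stage == "immature_total"])
  sel <- select_linear_range(egg, survival_by_temp = cohort)
  expect_equal(sel$temperature, c(20, 24, 28, 30))
})
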