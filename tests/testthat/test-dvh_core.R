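# DVH containers, file I/O and transforms.

test_that("csv dialect reads back what it describes, with unit conversion", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# structure=GTV", "# volume_cm3=10", "# dose_unit=Gy",
    "# volume_unit=cm3", "0,10.0", "1,10.0", "2,0.0"), f)
  d <- read_dvh_table(f, "csv")
  expect_length(d, 1L)
  expect_s3_class(d[[1]], "cdvh")
  expect_equal(d[[1]]$total_volume, 10)
  expect_equal(d[[1]]$role, "GTV")
  expect_equal(d[[1]]$volume, c(10, 10, 0))

  # same curve as percent + cGy must land on the identical object
  fp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# structure=GTV", "# volume_cm3=10", "# dose_unit=cGy",
    "# volume_unit=percent", "0,100", "100,100", "200,0"), fp)
  dp <- read_dvh_table(fp, "csv")
  expect_equal(dp[[1]]$dose, d[[1]]$dose)
  expect_equal(dp[[1]]$volume, d[[1]]$volume)

  # percent volumes without a declared structure volume is a hard error
  fb <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# structure=GTV", "# volume_unit=percent",
               "0,100", "1,50", "2,0"), fb)
  expect_error(read_dvh_table(fb, "csv"), "volume_cm3")
})

test_that("non-monotone cumulative volumes beyond tolerance name the bin", {
  expect_error(cdvh(c(0, 1, 2), c(10, 10.5, 0), structure = "GTV"),
               "increases at bin 2")
  # jitter within 1e-6 * total is clamped silently
  c <- cdvh(c(0, 1, 2), c(10, 10 + 5e-6, 0))
  expect_true(all(diff(c$volume) <= 0))
  expect_equal(c$total_volume, 10)
})

test_that("planner_export dialect tolerates separators and whitespace", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Structure: Lung_total   ",
    "Volume [cm3]: 3,251.4",
    "Dose [cGy]   Ratio of Total Structure Volume [%]",
    "     0      100.0   ",
    "  1000       40.0",
    "  2000        0.0"), f)
  d <- read_dvh_table(f, "planner_export")
  expect_equal(d[[1]]$role, "LUNG")
  expect_equal(d[[1]]$dose, c(0, 10, 20))
  expect_equal(d[[1]]$volume, 3251.4 * c(1, 0.4, 0))
})

test_that("csv writer is bit-reproducible through a read cycle", {
  set.seed(42)
  dvhs <- list(random_cdvh(role = "LUNG"), random_cdvh(role = "GTV"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dvh_csv(dvhs, f1)
  write_dvh_csv(read_dvh_table(f1, "csv"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("resample interpolates linearly and preserves fixed points", {
  c1 <- cdvh(seq(0, 2, by = 0.1), seq(10, 0, by = -0.5))
  r <- resample(c1, 0.05)
  expect_equal(r$dose[2] - r$dose[1], 0.05)
  shared <- match(round(c1$dose, 10), round(r$dose, 10))
  expect_equal(r$volume[shared], c1$volume)
  expect_equal(r$total_volume, c1$total_volume)
  # resampling onto the same grid is the identity
  expect_equal(resample(c1, 0.1)$volume, c1$volume)
  # closed form: V(D) = 10 (1 - D/2) gives V(1) = 5
  expect_equal(r$volume[abs(r$dose - 1) < 1e-12], 5)
})

test_that("cumulative/differential conversion telescopes and round-trips", {
  c1 <- cdvh(c(0, 1, 2), c(10, 10, 0), structure = "GTV")
  d <- cdvh_to_ddvh(c1)
  expect_equal(d$dose, c(0.5, 1.5))
  expect_equal(d$volume, c(0, 10))
  expect_equal(d$total_volume, c1$total_volume)

  # uniform-dose structure: all volume lands in one bin containing D*
  cu <- cdvh(seq(0, 3, 0.5), c(rep(7, 7)))
  du <- cdvh_to_ddvh(cu)
  expect_equal(sum(du$volume), 7)
  expect_equal(du$dose[du$volume > 0], 3.25)  # residual bin just above last edge

  # round trip is the identity on randomized monotone curves ending at zero
  set.seed(7)
  for (i in 1:10) {
    c0 <- random_cdvh(n_bins = sample(10:80, 1))
    back <- ddvh_to_cdvh(cdvh_to_ddvh(c0))
    expect_equal(back$dose, c0$dose)
    expect_equal(back$volume, c0$volume)
  }

  # empty structure stays empty; single bin gives a two-point cumulative
  expect_equal(ddvh_to_cdvh(ddvh(0.5, 0, 1))$volume, c(0, 0))
  one <- ddvh_to_cdvh(ddvh(0.5, 4, 1))
  expect_equal(one$dose, c(0, 1))
  expect_equal(one$volume, c(4, 0))
})

test_that("cohort averaging is an idempotent per-bin mean", {
  set.seed(11)
  c1 <- random_cdvh(role = "LUNG")
  expect_equal(average_cdvh(list(c1, c1), "absolute", bin_width = 0.5)$volume,
               c1$volume)

  # two curves with V(10 Gy) of 20% and 40% average to 30%
  a <- cdvh(seq(0, 20, 0.5), 100 * pmax(0, 1 - seq(0, 20, 0.5) / 12.5))
  b <- cdvh(seq(0, 20, 0.5), 50 * pmax(0, 1 - seq(0, 20, 0.5) / 50 * 3))
  expect_equal(v_at_dose(a, 10), 20)
  expect_equal(v_at_dose(b, 10), 40)
  avg <- average_cdvh(list(a, b), "percent")
  expect_equal(v_at_dose(avg, 10), 30)

  # averaged curve of randomized cohorts stays non-increasing
  coh <- replicate(6, random_cdvh(n_bins = sample(20:60, 1)), simplify = FALSE)
  expect_true(all(diff(average_cdvh(coh, "percent")$volume) <= 1e-12))

  # percent mode commutes with scalar volume rescaling
  c2 <- c1; c2$volume <- c2$volume * 3; c2$total_volume <- c2$total_volume * 3
  expect_equal(average_cdvh(list(c1), "percent")$volume,
               average_cdvh(list(c2), "percent")$volume)

  expect_error(average_cdvh(list(c1, random_cdvh(role = "GTV"))), "mixed roles")
})

test_that("V_x and mean dose match their closed forms", {
  line <- cdvh(seq(0, 2, 0.05), 10 * (1 - seq(0, 2, 0.05) / 2))
  expect_equal(v_at_dose(line, 1.0), 50)
  expect_equal(v_at_dose(line, 0), 100)
  expect_message(v0 <- v_at_dose(line, 99), "beyond")
  expect_equal(v0, 0)
  # v_at_dose is non-increasing in the threshold
  vs <- vapply(seq(0, 2, 0.1), function(t) v_at_dose(line, t), 0)
  expect_true(all(diff(vs) <= 1e-12))

  expect_equal(mean_dose(uniform_ddvh(12.5, 4)), 12.5)
  expect_equal(mean_dose(ddvh(c(10, 20), c(5, 5), 10)), 15)
  set.seed(3)
  d <- random_ddvh()
  expect_equal(mean_dose(d), sum(d$dose * d$volume) / sum(d$volume),
               tolerance = 1e-12)
  expect_error(mean_dose(ddvh(c(1, 2), c(0, 0), 1)), "zero total volume")
})
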