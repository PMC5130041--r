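# Lung NTCP and chest-wall mEUD models.

test_that("gEUD is the power mean with its limiting cases", {
  for (n in c(0.1, 0.5, 0.99, 1))
    expect_equal(geud(uniform_ddvh(18, 7), n), 18, tolerance = 1e-12)
  expect_equal(geud(ddvh(c(10, 20), c(5, 5), 10), 1), 15)  # n = 1 is mean dose
  set.seed(17)
  for (i in 1:8) {
    d <- random_ddvh()
    n <- runif(1, 0.05, 1)
    f <- d$volume / sum(d$volume)
    expect_equal(geud(d, n), sum(f * d$dose^(1 / n))^n, tolerance = 1e-10)
    expect_gte(geud(d, n), min(d$dose) - 1e-12)
    expect_lte(geud(d, n), max(d$dose) + 1e-12)
  }
})

test_that("LKB probit hits its midpoint and unit-slope points", {
  td50 <- 30.8; m <- 0.37; nv <- 0.99
  expect_equal(ntcp_lkb(uniform_ddvh(td50, 1000), td50, m, nv), 0.5)
  expect_equal(ntcp_lkb(uniform_ddvh(td50 * (1 + m), 1000), td50, m, nv),
               pnorm(1))
  expect_equal(ntcp_lkb(uniform_ddvh(0, 1000), td50, m, nv), pnorm(-1 / m))
  # strictly increasing under uniform dose scaling
  set.seed(23)
  d <- random_ddvh(role = "LUNG")
  hi <- d; hi$dose <- hi$dose * 1.3
  expect_gt(ntcp_lkb(hi, td50, m, nv), ntcp_lkb(d, td50, m, nv))
})

test_that("logistic lung model is a logit-linear function of mean dose", {
  d <- uniform_ddvh(10, 500)
  expect_equal(ntcp_fenwick_lung(d, c(-1.7, 0)), plogis(-1.7))
  expect_equal(ntcp_fenwick_lung(d, c(-0.126 * 10, 0.126)), 0.5)
  set.seed(29)
  for (i in 1:8) {
    a <- random_ddvh(role = "LUNG")
    b <- a; b$dose <- b$dose * runif(1, 1.05, 2)
    expect_gt(ntcp_fenwick_lung(b, c(-3.87, 0.126)),
              ntcp_fenwick_lung(a, c(-3.87, 0.126)))
  }
  expect_error(ntcp_fenwick_lung(d, c(1)), "coefficients")
})

test_that("hottest subvolume accumulates greedily from the top", {
  u <- hottest_subvolume(uniform_ddvh(22, 150), 100)
  expect_equal(u$total_volume, 100)
  expect_equal(u$dose[u$volume > 0], 22)

  d <- ddvh(c(10, 20, 30), c(60, 60, 60), 10)
  hot <- hottest_subvolume(d, 100)
  expect_equal(hot$total_volume, 100)
  expect_equal(hot$volume[hot$dose == 30], 60)
  expect_equal(hot$volume[hot$dose == 20], 40)  # boundary bin split
  expect_false(10 %in% hot$dose[hot$volume > 0])

  expect_message(whole <- hottest_subvolume(d, 500), "whole structure")
  expect_identical(whole, d)
  set.seed(37)
  for (i in 1:8) {
    r <- random_ddvh()
    v <- runif(1, 0.1, sum(r$volume))
    expect_equal(hottest_subvolume(r, v)$total_volume, v, tolerance = 1e-12)
  }
})

test_that("chest-wall mEUD reduces to known means and weighted power means", {
  for (w in c("none", "moderate", "strong"))
    expect_equal(meud_cw(uniform_ddvh(31, 140), weighting = w), 31,
                 tolerance = 1e-12)
  # weighting none, a = 1: mean dose of the hottest 100 cc
  d <- ddvh(c(10, 20, 30), c(60, 60, 60), 10)
  expect_equal(meud_cw(d, a_exponent = 1, weighting = "none"),
               (60 * 30 + 40 * 20) / 100)
  # two-bin hand-computed weighted power mean (moderate: w = D)
  hot <- c(60, 40); dose <- c(30, 20)
  expect_equal(meud_cw(d, 1, "moderate"),
               sum(dose * hot * dose) / sum(dose * hot), tolerance = 1e-10)
  # positive weight exponents can only pull the summary upward
  set.seed(41)
  for (i in 1:8) {
    r <- random_ddvh(n_bins = 30, bin_width = 2)
    sub <- runif(1, 1, sum(r$volume))
    expect_gte(meud_cw(r, 1, "moderate", subvolume = sub) + 1e-10,
               meud_cw(r, 1, "none", subvolume = sub))
  }
})
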