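# Tumor control probability models.

test_that("logistic TCP hits its midpoint, limits and closed form", {
  for (p in list(c(84.5, 1.5), c(51.9, 0.83), c(60, 1), c(30, 2.7)))
    expect_identical(tcp_logistic(p[1], p[1], p[2]), 0.5)
  expect_equal(tcp_logistic(1e9, 50, 1), 1, tolerance = 1e-6)
  expect_identical(tcp_logistic(0, 50, 1), 0)
  d <- 34 * 44 / 12
  expect_equal(tcp_logistic(d, 84.5, 1.5), 1 / (1 + (84.5 / d)^6))
})

test_that("covariate logistic TCP behaves as a logit-linear model", {
  u <- uniform_ddvh(50, 3)
  # intercept-only model is constant
  expect_equal(tcp_covariate_logistic(u, size = 2, coef = c(1.2, 0, 0)),
               plogis(1.2))
  # c0 chosen so the logit vanishes gives exactly 0.5
  c0 <- -(0.03 * 50 + (-0.5) * 2)
  expect_equal(tcp_covariate_logistic(u, 2, c(c0, 0.03, -0.5)), 0.5)
  # monotone in the dose summary when c1 > 0
  set.seed(21)
  for (i in 1:10) {
    d1 <- random_ddvh()
    d2 <- d1; d2$dose <- d2$dose * runif(1, 1, 3)
    expect_gte(tcp_covariate_logistic(d2, 2, c(0, 0.05, -0.3)),
               tcp_covariate_logistic(d1, 2, c(0, 0.05, -0.3)))
  }
  expect_error(tcp_covariate_logistic(u, size = NULL, coef = c(0, 1, 1)),
               "size covariate")
})

test_that("Webb-Nahum TCP matches its Poisson closed forms", {
  rho <- 1e8; alpha <- 0.30
  # sigma = 0, uniform dose on 1 cm^3: the dose solving rho V e^{-aD} = ln 2
  # gives exactly TCP = 0.5
  D50 <- log(rho * 1 / log(2)) / alpha
  expect_equal(tcp_webb_nahum(uniform_ddvh(D50, 1), alpha, 0, rho), 0.5,
               tolerance = 1e-12)
  # zero dose: essentially no kill
  expect_lt(tcp_webb_nahum(uniform_ddvh(0, 1), alpha, 0.1, rho), 1e-100)
  # percent-volume DVHs are rejected (clonogen count needs cm^3)
  pct <- uniform_ddvh(60, 100)
  pct$volume_unit <- "percent"
  expect_error(tcp_webb_nahum(pct, alpha, 0.1, rho), "absolute volumes")
})

test_that("Webb-Nahum quadrature agrees with a 1e6-node trapezoid oracle", {
  d <- ddvh(c(55, 60, 62, 65, 70), c(0.5, 2, 4, 2, 0.5), 1, role = "GTV")
  got <- tcp_webb_nahum(d, 0.30, 0.1, 1e8)
  oracle <- wn_trapezoid_oracle(d, 0.30, 0.1, 1e8, nodes = 1e6)
  expect_equal(got, oracle, tolerance = 1e-6)
  expect_gte(got, 0); expect_lte(got, 1)
})

test_that("Webb-Nahum collapses to the single-alpha form as sigma -> 0", {
  d <- ddvh(c(58, 62, 66), c(1, 3, 1), 2)
  expect_equal(tcp_webb_nahum(d, 0.30, 1e-6, 1e8),
               tcp_webb_nahum(d, 0.30, 0, 1e8), tolerance = 1e-6)
})

test_that("SF2 EUD is a survival-weighted dose with the right fixed points", {
  expect_equal(sf2_eud(uniform_ddvh(47.5, 9), 0.3), 47.5, tolerance = 1e-12)
  # two equal halves at 0 and D: closed form via SF2 = exp(-2 alpha)
  D <- 40; alpha <- 0.3; sf2 <- exp(-2 * alpha)
  two <- ddvh(c(0, D), c(5, 5), 1)
  expect_equal(sf2_eud(two, alpha), 2 * log(0.5 + 0.5 * sf2^(D / 2)) / log(sf2))
  # heterogeneity pulls EUD below the mean dose
  set.seed(13)
  for (i in 1:10) {
    d <- random_ddvh()
    expect_lte(sf2_eud(d, 0.3), mean_dose(d) + 1e-12)
  }
})

test_that("the five-model panel returns a median and respects zero dose", {
  params <- radbio_params()
  z <- uniform_ddvh(0, 5, role = "GTV")
  tz <- tcp_all_models(z, params = params)
  expect_lt(tz[["median"]], 1e-6)
  expect_lt(max(tz[c("martel", "webb_nahum", "eud", "nitin")]), 1e-6)

  g <- ddvh(c(120, 125, 130), c(1, 3, 1), 5, role = "GTV")
  t1 <- tcp_all_models(g, params = params)
  expect_true(all(t1 >= 0 & t1 <= 1))
  expect_equal(t1[["median"]],
               median(t1[c("martel", "fenwick", "webb_nahum", "eud", "nitin")]))
})

test_that("every TCP model is monotone under uniform dose scaling", {
  params <- radbio_params()
  set.seed(31)
  for (i in 1:5) {
    base <- random_ddvh(n_bins = 30, bin_width = 2, role = "GTV")
    base$dose <- base$dose + 40  # clinically relevant dose region
    lo <- tcp_all_models(base, size = 2, params = params)
    hi <- base; hi$dose <- hi$dose * runif(1, 1.05, 1.5)
    hi <- tcp_all_models(hi, size = 2, params = params)
    expect_true(all(hi >= lo - 1e-9))
  }
})
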