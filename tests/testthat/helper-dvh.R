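# Shared fixture builders (all in code; no stored data).

# Uniform-dose structure: all of `total` cm^3 at exactly `dose` Gy.
uniform_ddvh <- function(dose, total, bin_width = 0.05, role = "OTHER") {
  ddvh(dose, total, bin_width = bin_width, structure = "uniform", role = role)
}

# Random valid cumulative DVH on a uniform grid, ending at zero volume.
random_cdvh <- function(n_bins = 60, total = 10, bin_width = 0.5,
                        role = "OTHER") {
  drops <- stats::runif(n_bins)
  vol <- total * c(1, 1 - cumsum(drops) / sum(drops))
  cdvh(bin_width * (0:n_bins), vol, structure = "random", role = role)
}

# Random differential DVH (dense uniform grid, non-negative volumes).
random_ddvh <- function(n_bins = 40, bin_width = 0.5, role = "OTHER") {
  ddvh(bin_width * (seq_len(n_bins) - 0.5), stats::runif(n_bins),
       bin_width = bin_width, structure = "random", role = role)
}

# Brute-force trapezoid oracle for the population-averaged Webb-Nahum TCP.
wn_trapezoid_oracle <- function(d, alpha_mean, alpha_sigma, rho,
                                nodes = 1e6) {
  keep <- d$volume > 0
  v <- d$volume[keep]
  D <- d$dose[keep]
  a <- seq(0, alpha_mean + 8 * alpha_sigma, length.out = nodes + 1)
  surv <- exp(-outer(a, D)) %*% v            # sum_i v_i exp(-a D_i)
  tcp <- exp(-rho * as.numeric(surv))
  w <- stats::dnorm(a, alpha_mean, alpha_sigma)
  tw <- c(0.5, rep(1, nodes - 1), 0.5)       # trapezoid weights
  sum(tw * w * tcp) / sum(tw * w)
}
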