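# Normal-tissue models: lung NTCP (EUD-based LKB probit and a logistic
# mean-dose model) and chest-wall toxicity via a dose-weighted modified EUD
# over the hottest 100 cc.

#' Generalized equivalent uniform dose (gEUD)
#'
#' The power-mean dose summary of the LKB family,
#' \deqn{gEUD = \Big(\sum_i f_i D_i^{1/n}\Big)^{n},}
#' with fractional volumes \eqn{f_i} and volume-effect exponent `n_volume`.
#' `n_volume = 1` gives the mean dose (parallel organ); small `n_volume`
#' approaches the maximum dose (serial organ). Uniform dose is a fixed point.
#'
#' @param x A [ddvh] with positive total volume.
#' @param n_volume Volume-effect exponent in `(0, 1]`.
#' @return gEUD in Gy.
#' @export
geud <- function(x, n_volume) {
  stopifnot(inherits(x, "ddvh"), n_volume > 0, n_volume <= 1)
  if (x$total_volume <= 0) stop("gEUD undefined for zero total volume")
  f <- x$volume / x$total_volume
  sum(f * x$dose^(1 / n_volume))^n_volume
}

#' LKB lung complication probability
#'
#' EUD-based Lyman-Kutcher-Burman model with probit link:
#' \deqn{t = \frac{gEUD - TD_{50}}{m\, TD_{50}}, \qquad NTCP = \Phi(t).}
#' Exactly 0.5 at `gEUD == td50` and \eqn{\Phi(1) \approx 0.8413} one slope
#' unit above it.
#'
#' @param x Lung [ddvh] in EQD2.
#' @param td50 Uniform dose of 50% complication in Gy.
#' @param m Slope parameter (> 0).
#' @param n_volume Volume-effect exponent in `(0, 1]`.
#' @return Complication probability in `(0, 1)`.
#' @export
ntcp_lkb <- function(x, td50, m, n_volume) {
  stopifnot(td50 > 0, m > 0)
  g <- geud(x, n_volume)
  stats::pnorm((g - td50) / (m * td50))
}

#' Logistic mean-lung-dose complication probability
#'
#' Logit-linear model in a lung dose summary (default: mean lung EQD2 dose),
#' \deqn{NTCP = \frac{1}{1 + e^{-(c_0 + c_1 \bar{D})}}.}
#'
#' @param x Lung [ddvh] in EQD2.
#' @param coef Numeric coefficients `c(c0, c1)` (intercept, per-Gy slope).
#' @return Complication probability in `(0, 1)`.
#' @export
ntcp_fenwick_lung <- function(x, coef) {
  stopifnot(inherits(x, "ddvh"))
  if (length(coef) != 2L || anyNA(coef))
    stop("lung logistic model needs coefficients c(c0, c1)")
  stats::plogis(coef[1L] + coef[2L] * mean_dose(x))
}

#' Hottest subvolume of a differential DVH
#'
#' Walks bins from the highest dose downward accumulating exactly `volume`
#' cm^3, splitting the boundary bin proportionally (at its center dose).
#' Requests at or above the structure volume return the whole structure
#' (with a message).
#'
#' @param x A [ddvh] with absolute volumes.
#' @param volume Requested subvolume in cm^3.
#' @return A [ddvh] whose total volume is `min(volume, total volume)`
#'   exactly; zero-volume bins below the cut are dropped.
#' @export
hottest_subvolume <- function(x, volume) {
  stopifnot(inherits(x, "ddvh"), volume > 0)
  if (x$volume_unit != "cm3")
    stop("hottest_subvolume needs absolute volumes (cm3)")
  if (volume >= x$total_volume) {
    if (volume > x$total_volume)
      message(sprintf(
        "requested %.4g cc exceeds structure volume %.4g cc; using whole structure",
        volume, x$total_volume))
    return(x)
  }
  ord <- order(x$dose, decreasing = TRUE)
  v <- x$volume[ord]
  taken <- pmin(v, pmax(0, volume - c(0, cumsum(v)[-length(v)])))
  keep <- taken > 0
  d <- x$dose[ord][keep]
  o2 <- order(d)
  ddvh(d[o2], taken[keep][o2], bin_width = x$bin_width,
       structure = x$structure, role = x$role, volume_unit = x$volume_unit)
}

#' Modified equivalent uniform dose of the hottest chest-wall subvolume
#'
#' Dose-weighted EUD over the hottest `subvolume` cc (default 100 cc) of the
#' chest wall:
#' \deqn{mEUD = \left(\frac{\sum_i w_i f_i D_i^{a}}{\sum_i w_i f_i}\right)^{1/a},
#'   \qquad w_i = D_i^{b},}
#' where the weight exponent `b` comes from the named weighting preset
#' (`none`: b = 0, reducing exactly to the power-mean gEUD of the
#' subvolume; `moderate` / `strong` emphasise the hottest voxels). Uniform
#' dose is a fixed point for every weighting.
#'
#' @param x Chest-wall [ddvh] in EQD2 with absolute volumes.
#' @param a_exponent Power-mean exponent `a` (default 1: with `none`
#'   weighting, the mean dose of the hot subvolume).
#' @param weighting `"none"`, `"moderate"` or `"strong"`, or a single
#'   numeric weight exponent `b`.
#' @param subvolume Hottest subvolume in cm^3 (default 100).
#' @param weight_exponents Named mapping preset -> `b` (from the parameter
#'   file).
#' @return mEUD in Gy.
#' @export
meud_cw <- function(x, a_exponent = 1, weighting = "moderate",
                    subvolume = 100,
                    weight_exponents = c(none = 0, moderate = 1, strong = 2)) {
  stopifnot(inherits(x, "ddvh"), subvolume > 0, a_exponent > 0)
  b <- if (is.numeric(weighting)) weighting else {
    weighting <- match.arg(weighting, names(weight_exponents))
    unname(weight_exponents[weighting])
  }
  hot <- hottest_subvolume(x, subvolume)
  keep <- hot$volume > 0
  d <- hot$dose[keep]
  f <- hot$volume[keep] / hot$total_volume
  if (!length(d) || all(d == 0)) return(0)
  w <- d^b
  (sum(w * f * d^a_exponent) / sum(w * f))^(1 / a_exponent)
}
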