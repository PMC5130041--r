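# Linear-quadratic EQD2 conversion and iso-effective dose solving.

#' Fractionation schedule
#'
#' @param n_fractions Positive integer number of fractions.
#' @param dose_per_fraction Dose per fraction in Gy.
#' @return An object of class `"schedule"` with fields `n_fractions`,
#'   `dose_per_fraction`, `total_dose` and a display `id` such as `"1x34Gy"`.
#' @examples
#' schedule(1, 34)   # single-fraction 34 Gy
#' schedule(4, 12)   # 48 Gy in 4 fractions
#' @export
schedule <- function(n_fractions, dose_per_fraction) {
  n <- as.integer(n_fractions)
  stopifnot(n >= 1L, dose_per_fraction > 0)
  structure(
    list(n_fractions = n, dose_per_fraction = dose_per_fraction,
         total_dose = n * dose_per_fraction,
         id = sprintf("%dx%gGy", n, dose_per_fraction)),
    class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("Schedule %s: %d x %g Gy = %g Gy total\n",
              x$id, x$n_fractions, x$dose_per_fraction, x$total_dose))
  invisible(x)
}

#' Equivalent dose in 2 Gy fractions (EQD2)
#'
#' Linear-quadratic conversion
#' \deqn{EQD_2 = D \frac{d + \alpha/\beta}{2 + \alpha/\beta}, \quad d = D/n,}
#' the total dose of a 2 Gy/fraction course with the same biological effect
#' as `total_dose` Gy delivered in `n_fractions` equal fractions. Equals
#' `total_dose` exactly when the dose per fraction is 2 Gy.
#'
#' @param total_dose Total physical dose in Gy (vectorised, >= 0).
#' @param n_fractions Number of fractions (>= 1).
#' @param alpha_beta Tissue alpha/beta ratio in Gy (> 0).
#' @return EQD2 in Gy.
#' @examples
#' eqd2_point(34, 1, 10)    # single-fraction tumor dose
#' eqd2_point(48, 4, 10)
#' @export
eqd2_point <- function(total_dose, n_fractions, alpha_beta) {
  stopifnot(n_fractions >= 1, alpha_beta > 0)
  if (any(total_dose < 0)) stop("total_dose must be non-negative")
  d <- total_dose / n_fractions
  total_dose * (d + alpha_beta) / (2 + alpha_beta)
}

#' Convert a differential DVH to EQD2
#'
#' Applies [eqd2_point()] to every bin-center dose under the usual DVH
#' assumption that a bin receiving total physical dose `D` receives `D/n` per
#' fraction, then re-bins onto a uniform EQD2 grid by volume-conserving
#' deposition: each source bin's volume goes into the destination bin that
#' contains its mapped center (no splitting). Bin volumes, and hence the
#' total structure volume, are conserved exactly.
#'
#' @param x A [ddvh] in physical dose.
#' @param sched A [schedule].
#' @param alpha_beta Tissue alpha/beta in Gy.
#' @param bin_width Output EQD2 grid width in Gy (default 0.05).
#' @return A [ddvh] on the uniform EQD2 grid (dense; zero bins included).
#' @export
eqd2_dvh <- function(x, sched, alpha_beta, bin_width = 0.05) {
  stopifnot(inherits(x, "ddvh"), inherits(sched, "schedule"))
  mapped <- eqd2_point(x$dose, sched$n_fractions, alpha_beta)
  idx <- pmax(1L, floor(mapped / bin_width + 1e-9) + 1L)
  vols <- numeric(max(idx))
  agg <- rowsum(x$volume, group = idx)
  vols[as.integer(rownames(agg))] <- agg[, 1L]
  centers <- (seq_along(vols) - 0.5) * bin_width
  ddvh(centers, vols, bin_width = bin_width, structure = x$structure,
       role = x$role, volume_unit = x$volume_unit)
}

#' Total dose in a new fractionation with the same EQD2
#'
#' Solves `D (D/n + alpha/beta) = EQD2_ref (2 + alpha/beta)` in closed form
#' (positive root of the quadratic) for the `target_n`-fraction total dose
#' iso-effective with `ref_total` Gy in `ref_n` fractions. Inverse-consistent
#' with [eqd2_point()] to machine precision.
#'
#' @param ref_total Reference total dose in Gy.
#' @param ref_n Reference number of fractions.
#' @param target_n Target number of fractions.
#' @param alpha_beta Tissue alpha/beta in Gy.
#' @return Target total dose in Gy.
#' @examples
#' isoeffective_total_dose(15, 1, 4, 10)  # 23.59 Gy
#' @export
isoeffective_total_dose <- function(ref_total, ref_n, target_n, alpha_beta) {
  stopifnot(ref_total > 0, ref_n >= 1, target_n >= 1, alpha_beta > 0)
  rhs <- eqd2_point(ref_total, ref_n, alpha_beta) * (2 + alpha_beta)
  # D^2/target_n + alpha_beta * D - rhs = 0
  target_n * (-alpha_beta + sqrt(alpha_beta^2 + 4 * rhs / target_n)) / 2
}
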