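# DVH containers and transforms.
#
# Two S3 classes carry all dose-volume information through the pipeline:
#   "cdvh"  -- cumulative DVH: volume receiving >= dose, evaluated at uniform
#              bin edges starting at 0 Gy.
#   "ddvh"  -- differential DVH: volume per dose bin at edge-midpoint centers.
# Volumes are stored in absolute cm^3 (percent is a presentation concern;
# the Poisson TCP model needs absolute volumes for the clonogen count).

#' Structure roles recognised by the pipeline
#' @export
DVH_ROLES <- c("GTV", "PTV_MINUS_GTV", "LUNG", "CHEST_WALL", "OTHER")

#' Guess a structure role from its label
#'
#' Maps free-text structure labels from planning-system exports onto the
#' fixed role vocabulary used by the pipeline (`GTV`, `PTV_MINUS_GTV`,
#' `LUNG`, `CHEST_WALL`, `OTHER`).
#'
#' @param label Structure label, e.g. `"PTV-GTV"`, `"Lung_total"`.
#' @return One of [DVH_ROLES].
#' @export
infer_role <- function(label) {
  l <- toupper(trimws(label))
  if (grepl("PTV[-_ ]?GTV|PTV *MINUS *GTV|SHELL", l)) return("PTV_MINUS_GTV")
  if (grepl("GTV", l)) return("GTV")
  if (grepl("LUNG", l)) return("LUNG")
  if (grepl("CHEST|^CW$|CHESTWALL|CHEST[-_ ]?WALL", l)) return("CHEST_WALL")
  "OTHER"
}

#' Cumulative dose-volume histogram
#'
#' Builds a validated cumulative DVH. The dose axis must be a uniform grid
#' starting at 0 Gy; `volume[i]` is the absolute volume (cm^3, unless
#' `volume_unit = "percent"`) receiving at least `dose[i]`. Tiny
#' non-monotonicities (up to `1e-6 * total volume`, floating-point jitter in
#' planning-system exports) are clamped; larger violations are an error
#' naming the first offending bin.
#'
#' @param dose Numeric vector of bin-edge doses in Gy, starting at 0,
#'   strictly increasing with uniform spacing.
#' @param volume Numeric vector, same length, volume at-or-above each dose.
#' @param structure Structure label (free text).
#' @param role One of [DVH_ROLES]; inferred from `structure` by default.
#' @param volume_unit `"cm3"` (default) or `"percent"`.
#' @return An object of class `"cdvh"`.
#' @export
cdvh <- function(dose, volume, structure = "", role = infer_role(structure),
                 volume_unit = "cm3") {
  dose <- as.numeric(dose)
  volume <- as.numeric(volume)
  role <- match.arg(role, DVH_ROLES)
  if (length(dose) != length(volume))
    stop("dose and volume must have equal length")
  if (length(dose) < 2L)
    stop("a cumulative DVH needs at least two dose points")
  if (abs(dose[1L]) > 1e-12)
    stop("dose grid must start at 0 Gy")
  w <- diff(dose)
  if (any(w <= 0))
    stop("dose grid must be strictly increasing")
  if (max(abs(w - w[1L])) > 1e-9 * w[1L])
    stop("dose grid must be uniformly spaced (relative tolerance 1e-9)")
  total <- volume[1L]
  if (total < 0) stop("total volume must be non-negative")
  tol <- 1e-6 * max(total, .Machine$double.eps)
  inc <- diff(volume)
  bad <- which(inc > tol)
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf(
      "cumulative volume increases at bin %d (dose %.4g Gy, structure '%s') by %.4g",
      i + 1L, dose[i + 1L], structure, inc[i]))
  }
  volume <- cummin(pmax(volume, 0))  # clamp export jitter
  structure(
    list(dose = dose, volume = volume, structure = as.character(structure),
         role = role, volume_unit = match.arg(volume_unit, c("cm3", "percent")),
         total_volume = volume[1L]),
    class = "cdvh")
}

#' Differential dose-volume histogram
#'
#' @param dose Bin-center doses in Gy (uniform spacing `bin_width`).
#' @param volume Volume per bin (cm^3 unless `volume_unit = "percent"`),
#'   all non-negative.
#' @param bin_width Bin width in Gy.
#' @inheritParams cdvh
#' @return An object of class `"ddvh"`.
#' @export
ddvh <- function(dose, volume, bin_width, structure = "",
                 role = infer_role(structure), volume_unit = "cm3") {
  dose <- as.numeric(dose)
  volume <- as.numeric(volume)
  if (length(dose) != length(volume))
    stop("dose and volume must have equal length")
  if (any(volume < -1e-12 * max(sum(volume), 1)))
    stop("differential bin volumes must be non-negative")
  structure(
    list(dose = dose, volume = pmax(volume, 0), bin_width = as.numeric(bin_width),
         structure = as.character(structure),
         role = match.arg(role, DVH_ROLES),
         volume_unit = match.arg(volume_unit, c("cm3", "percent")),
         total_volume = sum(pmax(volume, 0))),
    class = "ddvh")
}

#' @export
print.cdvh <- function(x, ...) {
  cat(sprintf("Cumulative DVH '%s' [%s]: %d bins, %.4g-%.4g Gy, total %.4g %s\n",
              x$structure, x$role, length(x$dose), min(x$dose), max(x$dose),
              x$total_volume, if (x$volume_unit == "cm3") "cm3" else "%"))
  invisible(x)
}

#' @export
print.ddvh <- function(x, ...) {
  cat(sprintf("Differential DVH '%s' [%s]: %d bins of %.3g Gy, total %.4g %s\n",
              x$structure, x$role, length(x$dose), x$bin_width,
              x$total_volume, if (x$volume_unit == "cm3") "cm3" else "%"))
  invisible(x)
}

#' Resample a cumulative DVH onto a uniform grid
#'
#' Linear interpolation of the cumulative curve onto a uniform grid from 0 to
#' the maximum dose (rounded up to a bin edge). No smoothing; values at grid
#' points shared with the input are reproduced exactly and the total volume
#' is preserved (the grid always contains 0 Gy).
#'
#' @param x A [cdvh] object.
#' @param bin_width Target bin width in Gy (default 0.05, the working
#'   resolution of the pipeline).
#' @return A [cdvh] on the new grid.
#' @export
resample <- function(x, bin_width = 0.05) {
  stopifnot(inherits(x, "cdvh"), bin_width > 0)
  n_bins <- ceiling(max(x$dose) / bin_width - 1e-9)
  grid <- bin_width * (0:max(n_bins, 1L))
  vol <- stats::approx(x$dose, x$volume, xout = grid, rule = 2)$y
  cdvh(grid, vol, structure = x$structure, role = x$role,
       volume_unit = x$volume_unit)
}

#' Convert a cumulative DVH to a differential DVH
#'
#' Bin volumes are first differences of the cumulative curve,
#' `v[i] = V(d[i]) - V(d[i+1])`, placed at edge-midpoint centers. Any volume
#' still at or above the last edge becomes one extra residual bin just above
#' it, so the bin volumes always sum to the total volume exactly (telescoping).
#'
#' @param x A [cdvh] object.
#' @return A [ddvh] object.
#' @export
cdvh_to_ddvh <- function(x) {
  stopifnot(inherits(x, "cdvh"))
  m <- length(x$dose)
  w <- x$dose[2L] - x$dose[1L]
  v <- -diff(x$volume)
  centers <- x$dose[-m] + w / 2
  if (x$volume[m] > 0) {          # residual mass at/above the last edge
    v <- c(v, x$volume[m])
    centers <- c(centers, x$dose[m] + w / 2)
  }
  ddvh(centers, v, bin_width = w, structure = x$structure, role = x$role,
       volume_unit = x$volume_unit)
}

#' Convert a differential DVH back to a cumulative DVH
#'
#' Exact inverse of [cdvh_to_ddvh()] (reverse cumulative sum over a
#' contiguous uniform bin grid).
#'
#' @param x A [ddvh] whose bin centers form a contiguous uniform grid.
#' @return A [cdvh] object.
#' @export
ddvh_to_cdvh <- function(x) {
  stopifnot(inherits(x, "ddvh"))
  w <- x$bin_width
  if (length(x$dose) > 1L &&
      max(abs(diff(x$dose) - w)) > 1e-9 * w)
    stop("bin centers must form a contiguous uniform grid")
  edges <- c(x$dose - w / 2, x$dose[length(x$dose)] + w / 2)
  vol <- c(rev(cumsum(rev(x$volume))), 0)
  cdvh(edges, vol, structure = x$structure, role = x$role,
       volume_unit = x$volume_unit)
}

#' Average a cohort of cumulative DVHs bin by bin
#'
#' All curves are resampled to a common 0.05 Gy grid extended to the cohort
#' maximum dose (a curve contributes zero volume beyond its own maximum),
#' then averaged per bin: in `"percent"` mode each curve is first normalised
#' to its own total volume (matching per-structure cohort DVH plots), in
#' `"absolute"` mode raw cm^3 are averaged.
#'
#' @param cohort List of [cdvh] objects, all with the same role.
#' @param mode `"percent"` (default) or `"absolute"`.
#' @param bin_width Common grid width in Gy.
#' @return A [cdvh]; in percent mode its volumes are in % (total 100).
#' @export
average_cdvh <- function(cohort, mode = c("percent", "absolute"),
                         bin_width = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(cohort) >= 1L, all(vapply(cohort, inherits, TRUE, "cdvh")))
  roles <- unique(vapply(cohort, `[[`, "", "role"))
  if (length(roles) != 1L)
    stop("cannot average DVHs with mixed roles: ", paste(roles, collapse = ", "))
  dmax <- max(vapply(cohort, function(c) max(c$dose), 0))
  grid <- bin_width * (0:ceiling(dmax / bin_width - 1e-9))
  vals <- vapply(cohort, function(c) {
    v <- stats::approx(c$dose, c$volume, xout = grid, rule = 2)$y
    v[grid > max(c$dose) + 1e-12] <- 0   # missing tail = zero volume
    if (mode == "percent") v / c$total_volume * 100 else v
  }, numeric(length(grid)))
  vals <- if (is.matrix(vals)) rowMeans(vals) else vals
  cdvh(grid, vals, structure = sprintf("cohort_mean_%s", roles),
       role = roles,
       volume_unit = if (mode == "percent") "percent" else "cm3")
}

#' Volume receiving at least a threshold dose (V_x)
#'
#' Linearly interpolated percent of the structure volume at or above
#' `threshold` Gy. A threshold beyond the recorded grid returns 0 (with a
#' message).
#'
#' @param x A [cdvh] object.
#' @param threshold Dose threshold in Gy (>= 0).
#' @return Percent of the structure volume (0-100).
#' @export
v_at_dose <- function(x, threshold) {
  stopifnot(inherits(x, "cdvh"), threshold >= 0)
  if (x$total_volume <= 0) stop("structure has zero volume")
  if (threshold > max(x$dose) + 1e-12) {
    message(sprintf("threshold %.4g Gy beyond DVH grid (max %.4g Gy); returning 0",
                    threshold, max(x$dose)))
    return(0)
  }
  v <- stats::approx(x$dose, x$volume, xout = threshold)$y
  v / x$total_volume * 100
}

#' Mean dose of a differential DVH
#'
#' Volume-weighted average of the bin-center doses.
#'
#' @param x A [ddvh] object with positive total volume.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(x) {
  stopifnot(inherits(x, "ddvh"))
  if (x$total_volume <= 0) stop("mean dose undefined for zero total volume")
  sum(x$volume * x$dose) / x$total_volume
}
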