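# Seeded synthetic DVH cohort generator.
#
# Emulates a ~19-patient early-stage peripheral lung SBRT cohort planned
# under two schedules (default 1x34 Gy and 4x12 Gy): GTV volumes log-uniform
# over the clinical range 0.9-41.6 cm^3, GTV dose concentrated above 120% of
# prescription, a PTV-GTV margin shell honouring 95% PTV coverage at the
# prescription dose, lung DVHs with steep falloff and chest-wall DVHs
# intermediate between target and lung. Anatomy (volumes, curve shapes) is
# shared across the two schedules; doses scale with the prescription ratio
# plus small per-plan jitter, mimicking replanning variability. Dose shapes
# are parametric curves, not voxel simulations: the analysis consumes only
# DVHs, so curve families suffice to exercise every code path.

#' Specification of a synthetic two-schedule DVH cohort
#'
#' @param n_patients Number of patients (default 19).
#' @param seed Integer master seed; every patient/structure/schedule draws
#'   from its own counter-based substream, so adding patients never perturbs
#'   existing ones.
#' @param gtv_volume_range GTV volume range in cm^3, sampled log-uniformly
#'   (default `c(0.9, 41.6)`, the clinical T1-T2 span).
#' @param ptv_gtv_ratio_range Range of the PTV/GTV volume ratio (the margin
#'   shell volume is `(ratio - 1) * GTV`).
#' @param schedules List of two [schedule] objects (default 1x34 Gy, 4x12 Gy).
#' @param gtv_hotspot_factor Minimum GTV dose as a fraction of prescription
#'   (default 1.20, the rapid-falloff planning constraint).
#' @param ptv_coverage_quantile Fraction of the PTV at or above prescription
#'   (default 0.95, the normalisation rule).
#' @param lung_falloff Exponential-decay scale of the irradiated-lung
#'   cumulative DVH, in units of prescription dose (default 0.35).
#' @param cw_falloff Chest-wall decay scale, same units (default 0.30),
#'   intermediate between target plateau and lung falloff.
#' @param noise_sd Relative per-bin volume jitter applied to lung and
#'   chest-wall curves (default 0.02); target structures use curve-level
#'   jitter only so planning constraints hold exactly.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients = 19L, seed = 1L,
                        gtv_volume_range = c(0.9, 41.6),
                        ptv_gtv_ratio_range = c(2.1, 9.8),
                        schedules = list(schedule(1, 34), schedule(4, 12)),
                        gtv_hotspot_factor = 1.20,
                        ptv_coverage_quantile = 0.95,
                        lung_falloff = 0.35,
                        cw_falloff = 0.30,
                        noise_sd = 0.02) {
  stopifnot(n_patients >= 0, length(schedules) == 2L,
            all(vapply(schedules, inherits, TRUE, "schedule")),
            all(gtv_volume_range > 0), diff(gtv_volume_range) >= 0,
            all(ptv_gtv_ratio_range > 1),
            gtv_hotspot_factor > 1,
            ptv_coverage_quantile > 0, ptv_coverage_quantile < 1,
            lung_falloff > 0, cw_falloff > 0, noise_sd >= 0)
  if (ptv_coverage_quantile >= gtv_hotspot_factor)
    stop("ptv_coverage_quantile must lie below gtv_hotspot_factor")
  structure(as.list(environment()), class = "cohort_spec")
}

# Deterministic substream seed for (patient, structure index, arm);
# arm = 0 is the shared-anatomy stream. Kept below 2^31.
substream_seed <- function(seed, patient, struct_idx, arm) {
  (as.numeric(seed) * 1000003 + patient * 8191 + struct_idx * 127 + arm) %%
    2147483647
}

# Piecewise-linear non-increasing fraction curve f(x) on normalized dose x,
# defined by knots; clamped to [0,1] and forced monotone.
fraction_curve <- function(xgrid, kx, kf) {
  f <- stats::approx(kx, kf, xout = xgrid, rule = 2)$y
  cummin(pmin(pmax(f, 0), 1))
}

make_structure_cdvh <- function(role, label, total, kx, kf, rx, bin_width,
                                noise_sd = 0) {
  xmax <- max(kx)
  grid <- bin_width * (0:ceiling(xmax * rx / bin_width))
  f <- fraction_curve(grid / rx, kx, kf)
  if (noise_sd > 0) {
    f <- f * (1 + stats::rnorm(length(f), 0, noise_sd))
    f[1L] <- 1
    f <- cummin(pmin(pmax(f, 0), 1))
  }
  cdvh(grid, total * f, structure = label, role = role)
}

#' Generate a synthetic two-schedule DVH cohort
#'
#' Draws one `patient_plan` per patient per schedule according to the
#' generative model described in [cohort_spec()]. Fully reproducible from
#' the spec's seed. By construction every patient satisfies: GTV minimum
#' (hence mean) dose at least `gtv_hotspot_factor` times prescription; at
#' least `ptv_coverage_quantile` of the PTV (GTV plus margin shell) at or
#' above prescription; and all structures valid cumulative DVHs on the
#' 0.05 Gy grid.
#'
#' @param spec A [cohort_spec()].
#' @param bin_width Dose grid width in Gy (default 0.05).
#' @return A list of `patient_plan` objects (class `"dvh_cohort"`), each with
#'   fields `patient_id`, `schedule_id`, `schedule` and `structures` (a list
#'   mapping role to [cdvh]).
#' @export
generate_cohort <- function(spec, bin_width = 0.05) {
  stopifnot(inherits(spec, "cohort_spec"))
  plans <- list()
  shell_hold <- spec$ptv_coverage_quantile + 0.005  # margin over the quantile
  for (p in seq_len(spec$n_patients)) {
    # shared anatomy stream (arm 0)
    set.seed(substream_seed(spec$seed, p, 0, 0))
    lr <- log(spec$gtv_volume_range)
    v_gtv <- exp(stats::runif(1, lr[1], lr[2]))
    ratio <- stats::runif(1, spec$ptv_gtv_ratio_range[1], spec$ptv_gtv_ratio_range[2])
    v_shell <- v_gtv * (ratio - 1)
    v_lung <- max(2000, stats::rnorm(1, 3000, 400))
    v_cw <- max(200, stats::rnorm(1, 400, 60))
    h <- spec$gtv_hotspot_factor + stats::runif(1, 0, 0.02)
    shell_top <- h + stats::runif(1, 0.02, 0.08)
    a_lung <- stats::runif(1, 0.15, 0.30)   # irradiated lung fraction
    a_cw <- stats::runif(1, 0.50, 0.70)     # irradiated chest-wall fraction
    for (arm in 1:2) {
      sched <- spec$schedules[[arm]]
      rx <- sched$total_dose
      structures <- list()
      set.seed(substream_seed(spec$seed, p, 1, arm))
      jit <- stats::runif(1, -0.01, 0.01)   # plan-difference jitter (targets)
      structures$GTV <- make_structure_cdvh(
        "GTV", "GTV", v_gtv,
        kx = c(0, h, h + 0.15 + jit), kf = c(1, 1, 0), rx = rx,
        bin_width = bin_width)
      set.seed(substream_seed(spec$seed, p, 2, arm))
      jit <- stats::runif(1, -0.01, 0.01)
      structures$PTV_MINUS_GTV <- make_structure_cdvh(
        "PTV_MINUS_GTV", "PTV-GTV", v_shell,
        kx = c(0, spec$ptv_coverage_quantile, 1,
               (1 + shell_top) / 2, shell_top, shell_top + 0.07 + jit),
        kf = c(1, 1, shell_hold, 0.70, 0.10, 0), rx = rx,
        bin_width = bin_width)
      set.seed(substream_seed(spec$seed, p, 3, arm))
      s <- spec$lung_falloff
      xl <- seq(0, 1.05, length.out = 43)
      decay <- (exp(-xl / s) - exp(-1.05 / s)) / (1 - exp(-1.05 / s))
      low <- pmax(0, 1 - xl / 0.03)          # unirradiated lung drops out fast
      structures$LUNG <- make_structure_cdvh(
        "LUNG", "Lung", v_lung,
        kx = xl, kf = a_lung * decay + (1 - a_lung) * low, rx = rx,
        bin_width = bin_width, noise_sd = spec$noise_sd)
      set.seed(substream_seed(spec$seed, p, 4, arm))
      t <- spec$cw_falloff
      xc <- seq(0, 0.95, length.out = 39)
      decay <- (exp(-xc / t) - exp(-0.95 / t)) / (1 - exp(-0.95 / t))
      low <- pmax(0, 1 - xc / 0.03)
      structures$CHEST_WALL <- make_structure_cdvh(
        "CHEST_WALL", "ChestWall", v_cw,
        kx = xc, kf = a_cw * decay + (1 - a_cw) * low, rx = rx,
        bin_width = bin_width, noise_sd = spec$noise_sd)
      plans[[length(plans) + 1L]] <- structure(
        list(patient_id = sprintf("P%02d", p), schedule_id = sched$id,
             schedule = sched, structures = structures),
        class = "patient_plan")
    }
  }
  structure(plans, class = "dvh_cohort", spec = spec)
}

#' @export
print.patient_plan <- function(x, ...) {
  cat(sprintf("Patient plan %s / %s: structures %s\n", x$patient_id,
              x$schedule_id, paste(names(x$structures), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to a directory of DVH csv files
#'
#' One file per patient per schedule (all four structure blocks), plus a
#' `manifest.csv` listing `patient_id, schedule_id, file`. Files round-trip
#' bit-identically through [read_dvh_table()] / [write_dvh_csv()].
#'
#' @param cohort A `dvh_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written DVH file paths, invisibly.
#' @export
cohort_to_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(plan) {
    fn <- sprintf("%s_%s.csv", plan$patient_id, plan$schedule_id)
    write_dvh_csv(plan$structures, file.path(dir, fn))
    data.frame(patient_id = plan$patient_id, schedule_id = plan$schedule_id,
               file = fn, stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), schedule_id = character(),
               file = character())
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, manifest$file))
}

#' Read a cohort written by [cohort_to_files()]
#'
#' @param dir Directory containing `manifest.csv` and DVH csv files.
#' @return A `dvh_cohort` list of `patient_plan` objects.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  plans <- lapply(seq_len(nrow(manifest)), function(i) {
    dvhs <- read_dvh_table(file.path(dir, manifest$file[i]), "csv")
    names(dvhs) <- vapply(dvhs, `[[`, "", "role")
    m <- regmatches(manifest$schedule_id[i],
                    regexec("^([0-9]+)x([0-9.]+)Gy$", manifest$schedule_id[i]))[[1]]
    if (length(m) != 3L)
      stop("cannot parse schedule id: ", manifest$schedule_id[i])
    structure(
      list(patient_id = manifest$patient_id[i],
           schedule_id = manifest$schedule_id[i],
           schedule = schedule(as.integer(m[2]), as.numeric(m[3])),
           structures = dvhs),
      class = "patient_plan")
  })
  structure(plans, class = "dvh_cohort")
}
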