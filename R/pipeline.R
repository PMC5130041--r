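# End-to-end two-schedule comparison: per patient and structure
# resample -> differential -> EQD2 (tissue alpha/beta) -> dose metrics and
# TCP/NTCP/mEUD models; cohort aggregation as mean +/- s.d.; paired
# statistics with a normality-gated t-test / Wilcoxon fallback; headline
# between-schedule contrasts.

LUNG_V_THRESHOLDS <- c(5, 10, 20, 30, 40, 50, 60, 70)
CW_V_THRESHOLDS <- c(10, 20, 30, 40, 50, 60)

#' Paired comparison with a normality gate
#'
#' Paired, two-tailed Student's t-test when the paired differences pass a
#' Shapiro-Wilk normality check (p >= `alpha`), otherwise a Wilcoxon
#' matched-pair signed-rank test. Degenerate inputs (fewer than two pairs,
#' or zero-variance differences) return `NA` with a flag rather than a
#' p-value.
#'
#' @param a,b Equal-length numeric vectors of per-patient paired values.
#' @param alpha Significance level of the Shapiro-Wilk gate (default 0.05).
#' @return List with `n`, `test` (`"t"`, `"wilcoxon"` or `NA`), `p` and
#'   `flag` (`""`, `"n<2"` or `"zero-variance"`).
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L)
    return(list(n = n, test = NA_character_, p = NA_real_, flag = "n<2"))
  d <- a - b
  if (stats::sd(d) == 0)
    return(list(n = n, test = NA_character_, p = NA_real_, flag = "zero-variance"))
  normal <- if (n >= 3L) stats::shapiro.test(d)$p.value >= alpha else TRUE
  if (normal) {
    p <- stats::t.test(a, b, paired = TRUE)$p.value
    list(n = n, test = "t", p = p, flag = "")
  } else {
    p <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
    list(n = n, test = "wilcoxon", p = p, flag = "")
  }
}

#' Absolute and relative between-arm contrasts
#'
#' `abs_contrast` is the plain difference `a - b`; `rel_contrast` is the
#' percent difference `100 (a - b) / b` on baseline `b`. These are the
#' arithmetic behind the headline schedule contrasts (the higher-dose arm as
#' `a`, the fractionated baseline as `b`).
#'
#' @param a,b Numeric summary values (e.g. cohort means of a metric).
#' @return Numeric contrast (same units as the input for `abs_contrast`,
#'   percent for `rel_contrast`).
#' @export
abs_contrast <- function(a, b) a - b

#' @rdname abs_contrast
#' @export
rel_contrast <- function(a, b) 100 * (a - b) / b

structure_metrics <- function(plan, params, bin_width = 0.05) {
  ab <- params$alpha_beta
  sz <- if (!is.null(plan$structures$GTV))
    equivalent_sphere_diameter(plan$structures$GTV$total_volume) else NULL
  out <- list()
  add <- function(structure, metric, value)
    out[[length(out) + 1L]] <<- data.frame(
      patient_id = plan$patient_id, schedule_id = plan$schedule_id,
      structure = structure, metric = metric, value = value,
      stringsAsFactors = FALSE)
  eq <- function(role, alpha_beta) {
    d <- cdvh_to_ddvh(resample(plan$structures[[role]], bin_width))
    eqd2_dvh(d, plan$schedule, alpha_beta, bin_width)
  }
  g <- eq("GTV", ab$tumor)
  add("GTV", "D_mean", mean_dose(g))
  tcp <- tcp_all_models(g, size = sz, params = params)
  for (m in names(tcp)) add("GTV", paste0("TCP_", m), 100 * tcp[[m]])
  s <- eq("PTV_MINUS_GTV", ab$tumor)
  add("PTV-GTV", "D_mean", mean_dose(s))
  l <- eq("LUNG", ab$lung)
  add("Lung", "D_mean", mean_dose(l))
  lc <- ddvh_to_cdvh(l)
  for (v in LUNG_V_THRESHOLDS)
    add("Lung", sprintf("V%d", v), suppressMessages(v_at_dose(lc, v)))
  lkb <- params$ntcp$lkb
  n_lkb <- 100 * ntcp_lkb(l, lkb$td50, lkb$m, lkb$n_volume)
  n_fen <- 100 * ntcp_fenwick_lung(
    l, c(params$ntcp$fenwick_lung$c0, params$ntcp$fenwick_lung$c1))
  add("Lung", "NTCP_lkb", n_lkb)
  add("Lung", "NTCP_fenwick", n_fen)
  add("Lung", "NTCP_median", (n_lkb + n_fen) / 2)  # midpoint of the two models
  cw <- eq("CHEST_WALL", ab$chest_wall)
  add("ChestWall", "D_mean", mean_dose(cw))
  cwc <- ddvh_to_cdvh(cw)
  for (v in CW_V_THRESHOLDS)
    add("ChestWall", sprintf("V%d", v), suppressMessages(v_at_dose(cwc, v)))
  mp <- params$meud
  add("ChestWall", "mEUD", meud_cw(
    cw, a_exponent = mp$a_exponent, weighting = mp$weighting,
    subvolume = mp$subvolume_cc,
    weight_exponents = unlist(mp$weight_exponents)))
  do.call(rbind, out)
}

#' Run the two-schedule radiobiological comparison
#'
#' Executes the whole modeling chain on a cohort (a `dvh_cohort` or a
#' directory written by [cohort_to_files()]): per patient and structure,
#' resample to the 0.05 Gy grid, convert to a differential DVH, convert to
#' EQD2 with the tissue alpha/beta, then compute dose metrics (mean EQD2
#' dose; lung V5-V70; chest-wall V10-V60), the five TCP models with their
#' per-patient median, lung NTCP (LKB, logistic, midpoint median) and the
#' chest-wall mEUD. Aggregates mean +/- s.d. across patients per arm and
#' runs [paired_compare()] per metric. Patients missing a schedule or a
#' structure are skipped with a warning and counted in `n_excluded`.
#'
#' @param x A `dvh_cohort` from [generate_cohort()]/[read_cohort()], or a
#'   directory path.
#' @param params Parameter set from [radbio_params()].
#' @param bin_width Working dose-grid width in Gy (default 0.05).
#' @return An object of class `"comparison_report"` with fields
#'   `per_patient` (long data.frame of per-patient metric values), `summary`
#'   (per-metric mean/sd per arm plus paired-test results), `contrasts`
#'   (headline between-arm contrasts from [derived_contrasts()]), `arms`
#'   (arm identifiers, higher-dose-per-fraction arm first), `n_patients` and
#'   `n_excluded`.
#' @export
run_comparison <- function(x, params = radbio_params(), bin_width = 0.05) {
  if (is.character(x)) x <- read_cohort(x)
  stopifnot(inherits(x, "dvh_cohort") || is.list(x))
  roles_needed <- c("GTV", "PTV_MINUS_GTV", "LUNG", "CHEST_WALL")
  by_patient <- split(x, vapply(x, `[[`, "", "patient_id"))
  excluded <- 0L
  rows <- list()
  arms <- character()
  for (pid in names(by_patient)) {
    plans <- by_patient[[pid]]
    scheds <- vapply(plans, `[[`, "", "schedule_id")
    ok <- length(plans) == 2L && length(unique(scheds)) == 2L &&
      all(vapply(plans, function(p)
        all(roles_needed %in% names(p$structures)), TRUE))
    if (!ok) {
      warning("skipping patient ", pid, ": missing schedule or structure")
      excluded <- excluded + 1L
      next
    }
    for (plan in plans)
      rows[[length(rows) + 1L]] <- structure_metrics(plan, params, bin_width)
    arms <- union(arms, scheds)
  }
  if (!length(rows)) stop("no complete patients in cohort")
  per_patient <- do.call(rbind, rows)
  # higher dose-per-fraction arm first (the single-fraction arm in the
  # default design); the other arm is the contrast baseline
  dpf <- vapply(arms, function(a) {
    m <- regmatches(a, regexec("^([0-9]+)x([0-9.]+)Gy$", a))[[1]]
    as.numeric(m[3])
  }, 0)
  arms <- arms[order(-dpf)]
  summary <- summarise_report(per_patient, arms, params)
  rep <- structure(
    list(per_patient = per_patient, summary = summary, arms = arms,
         n_patients = length(unique(per_patient$patient_id)),
         n_excluded = excluded),
    class = "comparison_report")
  rep$contrasts <- derived_contrasts(rep)
  rep
}

summarise_report <- function(per_patient, arms, params) {
  alpha <- params$pipeline$normality_alpha
  if (is.null(alpha)) alpha <- 0.05
  keys <- unique(per_patient[, c("structure", "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- per_patient[per_patient$structure == keys$structure[i] &
                         per_patient$metric == keys$metric[i], ]
    wide <- stats::reshape(sub[, c("patient_id", "schedule_id", "value")],
                           direction = "wide", idvar = "patient_id",
                           timevar = "schedule_id")
    a <- wide[[paste0("value.", arms[1])]]
    b <- wide[[paste0("value.", arms[2])]]
    cmp <- paired_compare(a, b, alpha)
    data.frame(
      structure = keys$structure[i], metric = keys$metric[i],
      mean_a = mean(a), sd_a = stats::sd(a),
      mean_b = mean(b), sd_b = stats::sd(b),
      abs_diff = abs_contrast(mean(a), mean(b)),
      rel_diff_pct = if (mean(b) != 0) rel_contrast(mean(a), mean(b)) else NA_real_,
      n = cmp$n, test = if (is.na(cmp$test)) NA_character_ else cmp$test,
      p = cmp$p, flag = cmp$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", arms[1])
  names(out)[names(out) == "sd_a"] <- paste0("sd_", arms[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", arms[2])
  names(out)[names(out) == "sd_b"] <- paste0("sd_", arms[2])
  out
}

#' Headline between-schedule contrasts of a comparison report
#'
#' Recomputes, from the report's own summary table, the headline contrasts:
#' absolute difference of the cohort-mean cross-model median TCP and median
#' lung NTCP (percentage points), and relative differences of the
#' cohort-mean GTV and PTV-GTV mean EQD2 dose and chest-wall mEUD (percent,
#' baseline = the fractionated arm). Values are reported at full precision;
#' rounding to one decimal is a display concern.
#'
#' @param report A `comparison_report`.
#' @return Named numeric vector: `tcp_median_abs`, `ntcp_median_abs`,
#'   `meud_rel_pct`, `gtv_dmean_rel_pct`, `ptv_gtv_dmean_rel_pct`.
#' @export
derived_contrasts <- function(report) {
  s <- report$summary
  pick <- function(structure, metric) {
    r <- s[s$structure == structure & s$metric == metric, ]
    c(r[[3L]], r[[5L]])  # mean arm1, mean arm2
  }
  tcp <- pick("GTV", "TCP_median")
  ntcp <- pick("Lung", "NTCP_median")
  meud <- pick("ChestWall", "mEUD")
  gtv <- pick("GTV", "D_mean")
  shell <- pick("PTV-GTV", "D_mean")
  c(tcp_median_abs = abs_contrast(tcp[1], tcp[2]),
    ntcp_median_abs = abs_contrast(ntcp[1], ntcp[2]),
    meud_rel_pct = rel_contrast(meud[1], meud[2]),
    gtv_dmean_rel_pct = rel_contrast(gtv[1], gtv[2]),
    ptv_gtv_dmean_rel_pct = rel_contrast(shell[1], shell[2]))
}

#' @export
print.comparison_report <- function(x, digits = 1, ...) {
  cat(sprintf("Two-schedule radiobiological comparison: %s vs %s (baseline %s)\n",
              x$arms[1], x$arms[2], x$arms[2]))
  cat(sprintf("Patients analysed: %d (excluded: %d)\n\n",
              x$n_patients, x$n_excluded))
  s <- x$summary
  disp <- data.frame(
    structure = s$structure, metric = s$metric,
    a = sprintf("%.1f ± %.1f", s[[3L]], s[[4L]]),
    b = sprintf("%.1f ± %.1f", s[[5L]], s[[6L]]),
    test = ifelse(is.na(s$test), s$flag, s$test),
    p = ifelse(is.na(s$p), NA, sprintf("%.3f", s$p)))
  names(disp)[3:4] <- x$arms
  print(disp, row.names = FALSE)
  cat("\nHeadline contrasts (arm 1 vs arm 2):\n")
  ct <- x$contrasts
  cat(sprintf("  median TCP:  %+.1f percentage points\n", ct["tcp_median_abs"]))
  cat(sprintf("  median NTCP: %+.1f percentage points\n", ct["ntcp_median_abs"]))
  cat(sprintf("  CW mEUD:     %+.1f%% (relative)\n", ct["meud_rel_pct"]))
  cat(sprintf("  GTV D_mean:  %+.1f%% (relative)\n", ct["gtv_dmean_rel_pct"]))
  cat(sprintf("  PTV-GTV D_mean: %+.1f%% (relative)\n", ct["ptv_gtv_dmean_rel_pct"]))
  invisible(x)
}

#' Write a comparison report to CSV files
#'
#' Emits `per_patient.csv`, `summary.csv` and `contrasts.csv` into `dir`.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_patient, file.path(dir, "per_patient.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(contrast = names(report$contrasts),
               value = as.numeric(report$contrasts)),
    file.path(dir, "contrasts.csv"), row.names = FALSE)
  invisible(dir)
}
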