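---
title: "Radiobiological comparison of SBRT schedules: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiobiological comparison of SBRT schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbio)
```

## Scope and model of the data

`radbio` compares two SBRT fractionation schedules — by default a single
34 Gy fraction against 4 × 12 Gy — on radiobiological endpoints computed
from per-structure dose-volume histograms (DVHs). The package starts from
DVHs, not dose grids: contouring, plan optimization and dose calculation
are upstream of its scope. Four structures drive the analysis: the gross
target volume (GTV), the PTV−GTV margin shell, the whole lung and the
chest wall.

All volumes are stored internally in absolute cm³; percent is a
presentation concern. This is not cosmetic: the Webb–Nahum TCP model needs
the absolute clonogen count ρ·V per bin, so a percent-only DVH is a hard
error there rather than a silent renormalisation.

The cumulative convention is *volume receiving at least dose d*, evaluated
at bin lower edges on a uniform grid starting at 0 Gy; differential bins
sit at edge midpoints. With that convention the cumulative→differential
difference scheme telescopes exactly, so `cdvh_to_ddvh()` followed by
`ddvh_to_cdvh()` is the identity (bitwise, not just to tolerance) on
curves that fall to zero, and total volume is conserved by construction.
Any cumulative mass still present at the last recorded edge becomes one
residual differential bin just above it, which keeps uniform-dose
(delta-like) structures exact. Interpolation of cumulative curves is
always linear with no smoothing: it is the conservative, invertible choice
and makes V\_x and resampling fixed points testable in closed form.
Monotonicity violations up to 10⁻⁶ of the structure volume are clamped
silently (planning-system exports carry rounding jitter at that scale);
anything larger is an error naming the offending bin, because it indicates
a corrupted export rather than noise.

The working dose resolution is 0.05 Gy everywhere (resampling, EQD2
re-binning, cohort averaging). When cohort curves have different maxima
the common grid is extended, never truncated, a curve contributing zero
volume beyond its own maximum. Cohort-average DVHs default to percent
normalisation per structure, the convention of published cohort DVH
figures; absolute averaging is available.

## Linear-quadratic EQD2 conversion

Cross-schedule comparison uses the equivalent dose in 2 Gy fractions,

$$EQD_2 = D\,\frac{d + \alpha/\beta}{2 + \alpha/\beta}, \qquad d = D/n,$$

applied per DVH bin under the standard assumption that a bin receiving
total physical dose $D$ receives $D/n$ per fraction. Defaults are
α/β = 10 Gy for tumor (GTV and margin shell), 1.3 Gy for lung and 3 Gy for
chest wall, all overridable in the parameter file. The lung value of
1.3 Gy is lower than the conventional 3 Gy; it follows the
radiation-pneumonitis dose-response literature that the shipped lung NTCP
constants come from, and users comparing against 3 Gy-based analyses
should override it. No high-dose LQ modification (LQ-L, universal survival
curve) is applied: within the 1–4 fraction range modeled here the plain LQ
form is the accepted choice, and adding a transition dose would introduce
a parameter the shipped fits were not built with.

After the nonlinear dose map the DVH is re-binned onto a uniform 0.05 Gy
EQD2 grid by volume-conserving deposition: each source bin's volume lands
in the destination bin containing its mapped center, with no splitting.
This is exactly conservative and deterministic; the price is a
discretisation error bounded by half a bin (0.025 Gy) in any downstream
dose summary, negligible at 0.05 Gy resolution. Tests of the
"2 Gy/fraction plans are unchanged by conversion" identity therefore use a
half-bin tolerance at the DVH level, while the identity is exact at the
dose-point level.

The iso-effective total dose between fractionations solves
$D(D/n + \alpha/\beta) = EQD_2^{ref}(2+\alpha/\beta)$ as the positive root
of the quadratic, in closed form rather than iteratively — exactness and
determinism over generality. Round-tripping through `eqd2_point()` holds
to machine precision; the canonical worked pair is 15 Gy × 1 ↔ 23.59 Gy
in 4 fractions at α/β = 10.

## TCP models

Five families are evaluated on the EQD2 GTV DVH and summarised by their
per-patient median:

* **Logistic dose-response** (`tcp_logistic`), used by the Martel-type,
  Nitin-type and EUD-model responses:
  $TCP = 1/(1+(D_{50}/D)^{4\gamma_{50}})$. Exactly 0.5 at $D_{50}$.
* **Covariate logistic** (`tcp_covariate_logistic`): logit-linear in a
  dose summary and a tumor-size covariate. The size covariate defaults to
  the equivalent-sphere diameter of the GTV volume, the only size measure
  available when cohorts are described by volumes.
* **Webb–Nahum** (`tcp_webb_nahum`): Poisson cell kill
  $TCP(\alpha)=\prod_i \exp(-\rho v_i e^{-\alpha D_i})$ with clonogen
  density ρ = 10⁸ cm⁻³, averaged over a normal α distribution
  (mean 0.30 Gy⁻¹, s.d. 0.10 Gy⁻¹) truncated at α ≥ 0 and renormalised.
* **SF2-based EUD** (`sf2_eud`): the survival-weighted uniform dose
  $EUD = 2\ln(\sum_i f_i SF_2^{D_i/2})/\ln SF_2$, $SF_2 = e^{-2\alpha}$
  with α = 0.30 Gy⁻¹, fed into the logistic response. EUD is a
  uniform-dose fixed point and lies below the mean dose for heterogeneous
  DVHs — cold spots dominate tumor control.

Two numerical decisions matter here. First, the population average over α
uses fixed 256-node Gauss–Legendre quadrature on
$[\max(0, \alpha_m - 8\sigma_\alpha),\ \alpha_m + 8\sigma_\alpha]$,
renormalised by the quadrature of the truncated weight itself: fully
deterministic (no Monte Carlo, no seeds), reproducible to better than
10⁻⁶ against a brute-force 10⁶-node trapezoid, and the σ-scaled interval
keeps the rule accurate as σ → 0, where it converges to the single-α
closed form. Second, Poisson kill factors that underflow to zero are left
at zero — they are harmless in the integral and clamping them would bias
nothing.

The logistic-family models are dose-*point* fits, while the pipeline holds
whole DVHs; a summary must be chosen. The default is the mean EQD2 GTV
dose — the least-assumption summary for nearly uniform target doses — with
the SF2-EUD selectable per model via the `dose_summary_mode` config switch.
For SBRT target DVHs (narrow, hot) the two differ little; the switch
isolates the assumption rather than burying it.

Model constants are data, not code: `inst/extdata/model_params.yml` ships
every D₅₀/γ₅₀, coefficient and weighting preset with a per-value source
string, and `radbio_params()` accepts a replacement file. Several cited
fits print no exact coefficients in the secondary literature; those
entries are marked `approximate` in the file, and no numeric test in this
package anchors to them — tests pin the model *forms* (midpoints,
fixed points, monotonicity, closed-form oracles), which hold for any valid
parameter set.

## Normal-tissue models

Lung NTCP uses the EUD-based LKB probit,
$NTCP = \Phi\!\big((gEUD - TD_{50})/(m\,TD_{50})\big)$ with
$gEUD = (\sum_i f_i D_i^{1/n})^n$ (shipped constants TD₅₀ = 30.8 Gy,
m = 0.37, n = 0.99 — essentially a mean-lung-dose organ), alongside a
logistic model in mean lung EQD2 dose; the reported "median" lung NTCP is
the midpoint of the two models, the per-patient median of a two-model
panel.

Chest-wall toxicity is summarised by a modified EUD over the hottest
100 cm³:

$$mEUD = \left(\frac{\sum_i w_i f_i D_i^{a}}{\sum_i w_i f_i}\right)^{1/a},
\qquad w_i = D_i^{\,b},$$

where `b` comes from a named weighting preset (`none` b = 0, reducing
exactly to the power-mean gEUD of the subvolume; `moderate` b = 1, the
default; `strong` b = 2). The presets are parameter-file data. The hottest
subvolume walks bins from the top dose down, splitting the boundary bin
proportionally at its center dose — deterministic and exactly
volume-conserving; a request at or beyond the structure volume returns the
whole structure with a note. mEUD is reported as a dose in Gy: EUD-family
quantities are doses, and the between-schedule comparison uses relative
differences, which no unit reading affects. Rib-fracture risk is out of
scope — no accepted dose-response model exists for it.

## The synthetic cohort: what it does and does not show

`generate_cohort()` draws parametric DVH curves, not voxel simulations:
the analysis consumes only DVHs, so curve families suffice to exercise
every code path. Defaults encode the study conditions: 19 patients; GTV
volumes log-uniform on 0.9–41.6 cm³ (the clinical T1–T2 span, log-uniform
because tumor volumes are right-skewed); GTV dose concentrated in
[1.20, 1.35] × prescription (the rapid-falloff planning constraint that
the GTV always exceeds 120% of prescription); a margin shell built so that
at least 95% of the PTV receives the prescription dose (the plan
normalisation rule, enforced by construction with a 0.5-point margin);
lung DVHs as a truncated-exponential falloff (scale 0.35 in units of
prescription dose, ~15–30% of lung irradiated) over an unirradiated bulk;
chest-wall curves intermediate (scale 0.30, 50–70% irradiated, support to
95% of prescription). The two arms share anatomy — volumes and curve
shapes are drawn once per patient — and differ by the prescription dose
scale plus small plan-difference jitter (curve-level for targets, so the
constraints above survive; 2% per-bin relative noise for lung and chest
wall), mimicking replanning variability while preserving the
within-patient pairing the paired tests need. Randomness is counter-based:
each (patient, structure, arm) draws from its own derived seed, so
enlarging the cohort never perturbs existing patients.

Physical-dose falloff scales for lung and chest wall are calibrated
loosely to plausible V-metric ranges, not fitted to any cohort — real
plans vary with tumor position, and a chest wall abutting the PTV can see
far higher hot-subvolume doses than the generator's default support
produces. Consequently the end-to-end tests assert the *directional*
finding (per-patient TCP, lung NTCP and chest-wall mEUD all strictly
higher under 1 × 34 Gy, which emerges from the LQ model for any curve
shapes once bin doses sit above a few Gy) and the *structure* of the
output tables, never absolute cohort values: passing tests show the chain
is implemented correctly, not that the generator reproduces any clinic's
dosimetry.

## Pipeline and statistics

`run_comparison()` executes, per patient and structure: resample to
0.05 Gy → differential → EQD2 (tissue α/β) → metrics and models; then
aggregates mean ± s.d. across patients per arm. Cohort aggregation
defaults to the mean (matching how two-arm DVH summary tables are
conventionally built); the per-patient cross-model median is aggregated
the same way. Between-arm significance uses a paired, two-tailed t-test
gated by a Shapiro–Wilk normality check on the paired differences at
α = 0.05, falling back to the Wilcoxon matched-pair signed-rank test —
the fallback rule is standard, and Shapiro–Wilk is the concrete gate
chosen here (configurable via `pipeline.normality_alpha`). Every
comparison records n, the test used and the p-value at full precision;
"0.000" is display rounding only. Degenerate cases return `NA` with a
flag rather than a fabricated p-value: fewer than two pairs (`n<2`) or
zero-variance differences (identical arms). Patients missing a schedule
or structure are skipped with a warning and counted, never silently
imputed.

Headline contrasts are recomputed from the report's own summary table
(`derived_contrasts()`): absolute percentage-point differences for the
median TCP and median lung NTCP, relative percent differences (baseline:
the fractionated arm) for target mean EQD2 doses and chest-wall mEUD.
They are exposed as two trivial, separately testable helpers
(`abs_contrast`, `rel_contrast`) so the report's arithmetic is internally
consistent by construction.

## Problem sizes and limitations

The shipped tests run the full 19-patient, two-arm synthetic comparison
(~1500 EQD2 bins per structure) in a few seconds on one core; the
Webb–Nahum trapezoid cross-check uses 10⁶ nodes on a 5-bin DVH. Known
limitations: no DICOM RT-DOSE ingestion (DVHs are the entry point); no
repopulation/reoxygenation corrections (negligible over 1–4 fractions);
no rib-fracture endpoint; logistic-family TCP models are point fits
applied to a DVH summary; and the approximate parameter-file entries noted
above. None of these affect the package's invariants, but absolute
TCP/NTCP values should be read as model outputs under the shipped
parameter file, not clinical predictions.
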