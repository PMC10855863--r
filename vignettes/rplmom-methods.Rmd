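---
title: "Methods: dMoM normalization and cross-validated biomarker discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dMoM normalization and cross-validated biomarker discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rplmom)
```

## The problem

First-trimester maternal serum concentrations of placenta-derived proteins —
the free beta-subunit of hCG, PAPP-A and PlGF — change steeply with
gestational age, so raw concentrations of cases and controls sampled at
different gestational days are not comparable. The standard remedy in
prenatal screening is the multiple of median (MoM): each concentration is
divided by the population median concentration at the same gestational day.
`rplmom` implements this daily-MoM (dMoM) normalization from published
reference-median equations and evaluates how well the normalized markers,
alone and in panels, discriminate recurrent pregnancy loss (RPL) cases from
controls, using a repeated cross-validated logistic-regression protocol.

## Reference median curves

Each analyte's log10 daily median is a polynomial in $x = \mathrm{GA} - 77$
(gestational age in days); the free beta-hCG curve carries an extra
$3.152\,\log_{10}(\mathrm{GA}-40)$ term:

* PAPP-A: $0.1950 + 2.844\times10^{-2}x - 3.522\times10^{-4}x^2 + 1.244\times10^{-5}x^3$ (IU/L), valid 49–97 days;
* free beta-hCG: $-3.240 - 5.097\times10^{-2}x - 4.480\times10^{-4}x^2 + 3.152\log_{10}(\mathrm{GA}-40)$ (IU/L), valid 49–97 days;
* PlGF: $1.319 + 0.01506\,x - 1.363\times10^{-5}x^2 - 2.336\times10^{-7}x^3$ (pg/mL), valid 56–98 days.

The PAPP-A and PlGF medians increase strictly over their windows; the free
beta-hCG median rises to an interior maximum and then falls. Evaluated on
the integer-day grid, that maximum sits at day 70 (`argmax_daily_median`),
which is the package's operative answer: we evaluate the printed equations
verbatim and expose no maternal-weight or other covariate adjustment, since
the equations contain no such term.

Design choices at this layer:

* **Gestational age is integer days.** Week $w$ spans days $7w$ to $7w+6$;
  "<9 weeks" therefore means day 62 and below. Conversions are explicit;
  fractional days are rejected rather than rounded, to avoid silent
  day-boundary drift.
* **Out-of-window days are a hard error.** Cohort-level filtering
  (`filter_for_analysis`), not clamping, is the supported path; this
  mirrors per-analyte sample exclusion and is why a study's per-analyte
  sample sizes differ.

## Cohort schema and filtering

A cohort is a tibble with one row per subject: group (`RPL`/`CONTROL`),
gestational age at sampling (days, enrolment window 35–98), optional
demographics, and per-analyte serum concentrations. Concentrations below
the assay detection limits (free beta-hCG 0.16 IU/L, PAPP-A 0.004 IU/L,
PlGF 3.6 pg/mL) are retained but flagged; a strict mode excludes them. A
subject enters an analysis only if every analyte in the requested panel is
present and inside its reference window, so panel sample sizes shrink
monotonically as panels grow.

## The synthetic cohort generator

The patient-level data behind this kind of study are typically not
deposited, so the package ships a generator that emulates the statistical
structure the analysis assumes, making every downstream stage testable:

* gestational ages uniform on each group's sampling range (defaults:
  cases 42–91 days, controls 35–83 days; the empirical GA distribution of
  any particular study is not modelled);
* log2 dMoM drawn from a trivariate normal whose means are the log2 of the
  group- and window-specific central dMoMs. Defaults are the study-window
  means (e.g. free beta-hCG late window: cases 0.05, controls 1.2). The
  printed "mean dMoM" values are interpreted as central (geometric-mean)
  parameters of a log-normal dMoM, i.e. the mean of log2 dMoM is
  log2(location): dMoMs are conventionally log-normal, and matching
  arithmetic means would require knowing the dispersion first;
* per-analyte log2-scale SDs calibrated by `calibrate_sigma_from_auc`, the
  equal-variance binormal inversion
  $\sigma = |\log_2(\ell_C/\ell_R)|/(\sqrt{2}\,\Phi^{-1}(\mathrm{AUC}))$,
  from the whole-range single-marker dMoM AUCs (0.820, 0.880, 0.644), so
  those AUCs are recoverable end to end;
* a common pairwise correlation of 0.3 among the three log2 dMoMs. No
  serum-level correlation is published for these markers; weak positive
  co-regulation of placenta-derived proteins is plausible, and the value is
  an exposed parameter, not a hidden constant;
* concentrations back-computed as dMoM times the daily median (using the
  window-edge median outside an analyte's reference window, so that
  out-of-range records exist and exercise the filtering) and floored at the
  detection limits;
* maternal age normal per group (cases 37.2 ± 4.5, controls 30.1 ± 7.0
  years, truncated at 16); gravidity/parity/prior losses are constant
  group-typical fills, not modelled.

**Matching.** With matching enabled, every case must end up with at least
two controls sampled within 7 days of its gestational age; the generator
resamples control ages (preserving each moved control's dMoM by rescaling
its concentrations with the median ratio) until the rule holds. A case
older than the control range's maximum plus 7 days is unmatchable by
construction — with the default ranges this happens for case ages of 91
days — and raises an error naming the case rather than silently bending a
range. Disable matching or widen the control range when that is not the
behaviour you want.

**What the generator does not emulate:** assay measurement error as a
separate layer (it is absorbed into the log2-scale SD), GA-dependent
dispersion, non-log-normal tails, and the exact GA distribution of any real
cohort. Passing tests therefore show the pipeline's statistical machinery
is correct and calibrated, not that any particular clinical result holds.

## Group comparison

`compare_groups` defaults to the two-sided Mann–Whitney test: exact (full
enumeration of the U null, as implemented in `stats::wilcox.test`) when the
combined sample is at most 25 with no ties, and the normal approximation
with continuity correction otherwise; fully tied inputs report p = 1 with a
warning. A rank test is the defensible default for samples of 5–25 skewed
dMoMs, and Welch's t is available via `method = "welch_t"`. No multiple-testing correction is
applied — results are raw per-analyte/window p-values, starred at the
conventional 0.05/0.01/0.001 thresholds with boundary values mapping to
the less significant label.

## The discrimination protocol

Classifiers are logistic regressions on log2 dMoM (or log2 concentration)
features standardized to zero mean and unit SD. The fit is iteratively
reweighted least squares to a gradient max-norm of 1e-8 (cap 100
iterations), with an optional ridge penalty on the standardized
coefficients; complete separation under the unpenalized fit is detected
(stalled iteration or standardized coefficients beyond 10) and flagged
rather than silently shrunk. With case counts as low as 5 in a late-window
stratum, separation is a real occurrence; the ridge option
(`penalty = 1`) is the documented way to obtain finite coefficients there.

Evaluation is 50 runs of stratified random 5-fold cross-validation
(`run_repeated_cv`):

* folds are stratified by class — with few cases, unstratified folds
  frequently lack positives entirely;
* standardization statistics are computed on the training folds only and
  applied to the held-out fold, avoiding information leakage; a global
  mode exists behind `scale_mode = "global"` for sensitivity analysis;
* each run pools its out-of-fold scores into one ROC rather than averaging
  five fold-curves, because fold-wise curves with one or two positives are
  degenerate;
* each run's TPR is linearly interpolated onto the fixed FPR grid 0, 0.01,
  …, 1; the averaged curve is the pointwise mean (and SD) of sensitivities
  across runs, enforced monotone after averaging;
* the reported AUC is the arithmetic mean of the 50 per-run trapezoidal
  AUCs; the trapezoid of the averaged curve is also emitted
  (`auc_of_mean_curve`) since the two summaries differ slightly;
* runs whose split leaves a single-class training set are redrawn with the
  next seed, with a message.

Sensitivities are read off the averaged curve at 5% and 10% FPR, and
likelihood ratios follow as LR+ = TPR/FPR and LR− = (1−TPR)/(1−FPR); these
identities hold exactly in every report row.

The fourteen published fixed-coefficient models (single markers and
combinations, on concentration and dMoM scales) are available through
`printed_models()` / `evaluate_printed_model()`, which apply the printed
affine expressions directly to log2 inputs without standardization.

## Numerical and testing choices

Problem sizes were chosen so the full test suite runs in well under a
minute: parameter recovery uses 5 000 subjects per group; calibration
closure and null checks use 500–2 000 per group; the end-to-end AUC
recovery checks run the full 50×5-fold protocol on binormal cohorts of 500
subjects per group and compare the mean CV AUC (averaged over three cohort
draws, to separate method bias from single-cohort sampling noise, whose SD
is about 0.01–0.017 at this size) against the calibrated targets within
±0.02. Monte-Carlo tolerances elsewhere are 3 standard errors with the
Hanley–McNeil formula for AUC. The exact Mann–Whitney path is verified
against a brute-force enumeration oracle for all group sizes with
$n_1+n_2 \le 12$, and the trapezoidal AUC against a concordance-count
double loop up to $n = 50$ and against an independent ROC implementation
(pROC).

## Known limitations

* The generator's uniform GA and constant demographic fills are
  deliberate simplifications; do not use it to study GA-distribution or
  covariate effects.
* With matching enabled, some seeds are infeasible under the default
  ranges (see above) and error out by design.
* `evaluate_printed_model` reproduces published log-odds expressions; it
  does not provide calibrated probabilities for new populations.
* Detection-limit flooring slightly censors the lowest dMoM tail (a few
  percent of draws for the low-location case windows), which the
  parameter-recovery tests account for with a censored-normal expectation.
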