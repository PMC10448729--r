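---
title: "Specimen adequacy and analytical sensitivity for MRD testing by NGF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specimen adequacy and analytical sensitivity for MRD testing by NGF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdflow)
library(dplyr)
```

## The measurement problem

Next-generation flow cytometry (NGF) for multiple myeloma counts malignant
plasma cells (MM-PCs) among ~10⁷ nucleated bone-marrow events, reporting
minimal residual disease (MRD) as a fraction of the order 10⁻⁴–10⁻⁶. Two
specimen-level failure modes dominate the error budget at that scale:

* **Low analytical input.** The nominal 10⁻⁶ sensitivity presumes at least
  10 × 10⁶ acquired nucleated events (≥ 5 × 10⁶ per staining tube, merged for
  analysis). A smaller acquisition simply cannot contain the 10 events that
  define a detection at 10⁻⁶.
* **Hemodilution.** An aspirate contaminated with peripheral blood contains
  proportionally fewer marrow-resident cells. The marrow is still being
  assayed — but a smaller share of each event is marrow, so rare marrow
  populations are under-sampled and a negative call overstates sensitivity.

`mrdflow` implements the quantitative workflow around both: input adequacy
and revised detection limits (`assess_input()`, `compute_revised_lod()`),
hemodilution classification from mast-cell content
(`classify_hemodilution()`, `compute_lln()`), MRD calls with burden bands
(`call_mrd()`), blank-based assay performance (`compute_blank_stats()`,
`sensitivity_scan()`), and adequacy-qualified reporting
(`render_report()`, `summarize_cohort()`).

## Blank statistics and detection capability

At a targeted virtual sensitivity $t$, specimens quantifying below $t$ are
MRD negative; their MM-PC quantifications form the blank set. With blank
sample mean $\bar{x}_B$ and sample SD $\sigma_B$ (always the $n-1$
denominator; the source material is silent and the sample-variance convention
is fixed here once):

$$\mathrm{LOB} = \bar{x}_B + 1.6\,\sigma_B, \quad
  \mathrm{LOD} = \bar{x}_B + 3\,\sigma_B, \quad
  \mathrm{LLOQ} = \bar{x}_B + 10\,\sigma_B,$$

the background, analytical and functional sensitivity of the assay. Note the
blank multiplier is 1.6 exactly — the value used in the clinical write-up of
this assay family — rather than the conventional one-sided 95 % normal
quantile 1.645; `compute_blank_stats(lob_z = 1.645)` restores the
conventional choice. The ordering LOB < LOD < LLOQ is automatic whenever
$\sigma_B > 0$, and all three scale linearly with the blank values
(scale equivariance), both of which are property-tested.

Two decisions matter in assembling blanks (`collect_blanks()`):

* The filter is *strictly* below $t$; a specimen exactly at threshold is a
  detection.
* Zero-count specimens are genuine blanks and are **included** by default.
  Excluding them (supported via `exclude_zeros = TRUE` for comparison with
  pipelines that drop zeros) biases $\bar{x}_B$ upward.

## The sensitivity scan and the achievable sensitivity

A single cohort yields exactly one virtual LOD per target, so "the RMSE of
the virtual LOD against its target" needs a replication set; the package
defines it over bootstrap resamples of the blank set:

$$\mathrm{RMSE}(t) = \sqrt{\tfrac{1}{B}\sum_b \left(\mathrm{vLOD}_b(t) - t\right)^2},$$

with $B$ = 200 by default, seeded and fully deterministic given the seed.
This resampling construction is a package design choice — the defining text
does not state the averaging set — and is flagged here prominently;
`resample = FALSE` reports the single-cohort deviation
$|\mathrm{vLOD}(t) - t|$ instead. Closed forms pin the implementation down:
an all-zero blank set gives $\mathrm{vLOD} \equiv 0$ and
$\mathrm{RMSE}(t) = t$ exactly.

The default grid is $10^{-5 - 0.1k}$ for $k = 0\ldots13$ (down to
$10^{-6.3} \approx 0.5 \times 10^{-6}$, the resolution floor at which a
clonal cluster can still reproducibly be resolved), with $0.9 \times 10^{-6}$
spliced in: that conventional reporting point does not lie on a 0.1-log grid,
an internal inconsistency of the published grid description that cannot be
resolved from the text, so the package keeps the log grid and appends the
cited point. Grid points with fewer than two blanks are skipped with a
warning.

**Selection rule** (`select_achievable_sensitivity()`): walking coarse →
fine, find the first grid point whose RMSE falls more than 2 % (the
`rel_tolerance` default) below the running minimum of all coarser points
*and* keeps decreasing at the next point; the achievable sensitivity is the
threshold immediately preceding that break. No qualifying drop means the
finest threshold is returned. The two-sided condition (relative drop plus
continued decrease) keeps single noisy bootstrap estimates from triggering a
break. Fewer than three usable points is an error: a break cannot be
located.

## Revised LOD, MRD calls and reporting

`compute_revised_lod(input) = 10 / input` is the sensitivity attainable with
a short acquisition; at the nominal 10⁷ events it is exactly 10⁻⁶, and it is
strictly antitone in the input. The per-specimen *effective sensitivity* is
the coarser of the nominal assay LOD and the revised LOD.

Status semantics at threshold $t$ deserve a precise statement because the
three obvious formulations disagree:

* **positive** iff the MM-PC fraction ≥ $t$ (closed lower bound: ten cells
  in 10⁷ *is* positive at 10⁻⁶). Detection is never suppressed by adequacy
  problems — a degraded assay that still finds disease has found disease.
  This keeps positivity monotone: positive at $t$ implies positive at every
  finer threshold, and the cohort positivity rate is non-decreasing as the
  threshold is refined.
* **not_evaluable** iff the fraction is below $t$ but the effective
  sensitivity is coarser than $t$: disease cannot be ruled out at the
  requested level.
* **negative** otherwise.

Burden bands are defined on the count rescaled to a 10⁷ denominator,
`round(events × 10⁷ / input)`: ultra-low 5–9, low 10–19, high > 100; the
unnamed 20–100 gap between the published bands is called `intermediate`
here, and below 5 no band is assigned. Serial transitions between low and
high bands within a follow-up window (`classify_transition()`) are the
in-vivo check that near-limit counts are real; a transition ending or
starting in the ultra-low/low bands without phenotypic and clonal
concordance is flagged as a suspected false positive.

Reporting (`render_report()`) then applies the clinical rules: positives are
always reported (with caveats); an unevaluable negative is reported either
as *negative at reduced sensitivity* — stating the sensitivity actually
achieved, which is the revised LOD whenever one exists — or as *not
evaluable*, a laboratory policy the text leaves open and the
`negative_policy` argument exposes; a hemodiluted negative is likewise
qualified. The three caveat strings are fixed package wording; the principle
(state the degradation, do not suppress the result) is the substantive
content.

## Hemodilution thresholds and the LLN

The default policy uses cohort-level mast-cell cut-offs: adequate ≥ 0.0048 %
(the average lower limit of normal across clinical time points), marginal
≥ 0.002 %, suboptimal below. Because mast content is strongly time-point
dependent (≈ 0.004 % early after therapy vs ≈ 0.015 % in late maintenance),
`compute_lln()` computes per-group limits $\max(0, \mu - \sigma)$ with the
grouping exposed: published cut-offs depend on the grouping used, and the
published group statistics are not fully mutually consistent, so the package
treats both thresholds as configurable policy (`hemodilution_policy()`)
rather than constants. The LLN is floored at zero because early-time-point
SDs exceed their means; a negative fraction is meaningless.

## What the synthetic cohort emulates

`generate_cohort()` is first-class, tested code, not a fixture. Per
specimen:

| Quantity | Model | Default source |
|---|---|---|
| time point | categorical | milestone mix of a 556-specimen clinical series (28/30/19/11/12 %) |
| route | categorical | 89.4 % bedside iliac, 10.6 % CT-guided |
| cellularity | log-normal, moment-matched | 11.5 ± 7.7 × 10⁶ cells/mL |
| viability | normal clipped to (0, 1] | 0.909 ± 0.09 |
| aspirate volume | normal, ≥ 2 mL | 5.0 ± 1.3 mL (two pooled syringes) |
| mast fraction | log-normal per time point | 0.0038 ± 0.0056 % early, 0.0130 ± 0.0065 % (1 y), 0.0155 ± 0.016 % late |
| N-PC fraction | log-normal | 0.25 ± 0.20 % (typical normal plasma-cell content; chosen, no published value) |
| disease burden | zero-inflated log-normal per time point | medians 0.0059 / 0.0005 / 0.0007 / 0.0014 / 0.0028 %, `burden_log_sd = 2` |
| MRD-negative probability | structural zero | 0.24 / 0.35 / 0.35 / 0.30 / 0.25 |
| dilution $d$ | Beta per route | bedside (0.7, 4.0), CT (2.5, 1.8) |
| event counts | multinomial given acquired events | exact, via sequential binomials |

Log-normal families are dictated by the data shape: the published SDs are of
the order of (or above) the means for strictly positive quantities, which
rules out normal models. Burden zero-inflation encodes true MRD negativity;
`burden_log_sd = 2` makes the published 0–9.3 % range plausible at n ≈ 556.
The 2-year and beyond burden medians are chosen (doubling yearly) to encode
gradual regrowth during maintenance; only the first three medians are
published.

**Mixing model.** With dilution $d$ (blood fraction) and spill $s_p$ (the
share of population $p$ that also circulates in blood), the observed
fraction is $f_p^{obs} = f_p (1 - d(1 - s_p))$. Defaults
$s_{mast} = 0 \le s_{npc} = 0.05 \le s_{mm} = 0.35$: mast cells are fully
marrow-resident, normal plasma cells nearly so, and MM-PCs — which
up-regulate adhesion molecules and are retained by the marrow matrix — are
depleted least. The ordering is enforced by config validation.

**Dilution severity** is anchored to two published observations: CT-guided
aspirates carry roughly half the mast content of bedside ones
(0.004 vs 0.008 %), which under the mixing model fixes
$(1 - E[d_{ct}]) / (1 - E[d_{bed}]) \approx 0.5$; and heavy hemodilution
reaches ~9 parts blood to 1 part marrow, so the Beta laws must carry mass at
large $d$. Beta(0.7, 4.0) (mean ≈ 0.15) and Beta(2.5, 1.8) (mean ≈ 0.58)
satisfy both. Much milder dilution laws would make mast content an
essentially uninformative proxy for dilution — inconsistent with the strong
published mast–dilution relationships.

**Calibration.** The configured mast summaries are *observed* (diluted)
values; the generator divides them by the config-implied mean depletion
$\sum_r w_r (1 - E[d_r](1 - s_{mast}))$ to obtain undiluted marrow levels,
so the simulated observed mast distribution matches the configured
summaries. Burden and N-PC levels are left uncalibrated; the resulting
~10–15 % downward bias is below the precision of the corresponding published
summaries.

**Ground truth** (true dilution and undiluted fractions) is emitted in a
sidecar table (`cohort_truth()`), not in the specimen schema: a real
laboratory never observes it, and QC operations are validated against it
without leaking it into the pipeline input.

**What is *not* emulated:** per-event fluorescence and gating, FCS output,
patient-level longitudinal correlation (specimens are independent draws, so
serial-transition analyses need hand-built cases), inter-operator and
inter-instrument variation, and any daratumumab effect beyond an exposure
flag. Passing tests on this cohort therefore validate the *analysis
pipeline's* logic and statistics, not the biology of any particular clinical
population; in particular the upper burden tail is lighter than a real
relapse-containing series, so simulated positivity at coarse thresholds
(≈ 11 % at 10⁻⁴) sits below typical clinical rates (≈ 30 %).

## Numerical and testing choices

* Fractions are dimensionless internally; percent appears only at I/O
  boundaries (`percent_to_fraction()` / `fraction_to_percent()`), because
  published detection limits mix the 0.00019-percent and 1.9 × 10⁻⁶ scales.
* Rates are kept at full precision and rounded half-up to one decimal only
  for display; sensitivities print at 3 significant figures.
* Determinism: the generator consumes `withr::local_seed(config$seed)`; the
  scan seeds its resampling the same way; `run_pipeline()` writes a manifest
  with MD5 checksums and no timestamps, so reruns are byte-identical.
* Degenerate inputs: `burden_log_sd = 0` collapses the burden law onto its
  median; an all-constant blank set collapses LOB = LOD = LLOQ onto the
  mean; blank sets of size < 2 and scan grids with < 3 usable points are
  errors, not silent results.
* Test problem sizes are chosen for tight Monte-Carlo bounds at interactive
  runtimes: 10⁵ draws for burden-median recovery (±5 %), 10⁴ specimens for
  moment recovery (3 closed-form standard errors) and for the
  dilution-ordering check across QC categories, 556 for the
  cohort-direction checks, and 100 replicates × 400 bootstrap resamples at
  n = 300 for detection-limit recovery.
* The detection-limit recovery check draws blanks from a log-normal with SD
  half the mean. Under much stronger skew the *percentile bootstrap
  interval itself* under-covers scale statistics — a known property of
  percentile intervals, not a defect of the estimator — so the moderate-skew
  law is the meaningful study condition for validating the package's
  machinery.
* The "normal plasma cells track mast depletion more steeply than malignant
  ones" direction is asserted via Spearman rank correlation of per-specimen
  fractions: with a zero-inflated, four-decade-heavy-tailed burden, raw
  linear regression slopes at n = 556 are dominated by a handful of
  high-burden specimens and do not stabilise, while the rank version
  captures the same direction robustly.

## Known limitations

* The bootstrap-RMSE construction behind the scan is one defensible reading
  of an under-specified procedure; selection results should be read
  qualitatively (where does tracking break down), not as a certified limit.
* Cohort-level hemodilution thresholds conflate time-point-specific
  biology; per-time-point LLN policies are supported and preferable when
  group sizes allow.
* The generator draws specimens independently; longitudinal MRD kinetics,
  relapse dynamics and repeated-measures correlation are out of scope.
* `classify_transition()` takes phenotype/clonality concordance as an input
  boolean; computing concordance from marker data is vendor-software
  territory and deliberately outside the package.
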