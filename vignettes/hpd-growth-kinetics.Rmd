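---
title: "Growth dynamics, RECIST response and hyperprogression: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth dynamics, RECIST response and hyperprogression: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hpdkinetics)
library(dplyr)
```

This vignette is the package's account of its science: the measurement
model behind each stage, the conventions and thresholds it fixes, why they
are fixed that way, and what the synthetic cohort does and does not
emulate. Everything quantitative shown here is computed by the package at
build time of this document or verified by the test suite; nothing is
asserted from memory.

## 1. The measurement chain

The package targets retrospective immuno-oncology analyses of the kind run
on advanced hepatocellular carcinoma cohorts treated with or without PD-1
blockade. Its unit of raw data is the *lesion measurement*: one longest
diameter (mm) for one lesion of one patient at one time, expressed in
months relative to therapy start (negative = pre-baseline). Everything
else — response categories, progression-free survival (PFS),
growth-dynamics metrics, the hyperprogression label, and the cohort-level
statistics — is derived from this table plus a patient table (arm,
treatment line, follow-up) and a gene-level alteration table.

All times are months; day-denominated inputs should be divided by the mean
Gregorian month of `days_per_month()` = 30.4375 days. This constant lives
in exactly one place.

## 2. RECIST 1.1 engine

`select_target_lesions()` takes, per patient, the largest baseline lesions
up to five overall and two per organ, with ties broken lexicographically by
lesion id so that re-runs are deterministic. The baseline measurement of a
lesion is the one at or before therapy start closest to it. New lesions are
never targets.

`tumor_burden_series()` computes S, the sum of target-lesion longest
diameters, per assessment. If a target lesion was not read at a time where
others were, S is *not evaluable* (NE) at that time: a partial sum would
understate burden and could fake a response.

`recist_assessments()` applies the standard thresholds per post-baseline
timepoint:

* **PD** — a new lesion, or S ≥ 120% of the nadir *and* S − nadir ≥ 5 mm;
* **CR** — S = 0 without a new lesion;
* **PR** — S ≤ 70% of baseline (unless PD);
* **SD** — otherwise; **NE** — burden not evaluable.

The nadir is the minimum evaluable S at or before the current assessment,
*including* baseline — so progression can be called at the first
on-treatment scan — and including the current value, which makes the
percent-from-nadir change of a new minimum zero by construction. NE
assessments are skipped for nadir tracking and best overall response but do
not terminate evaluation; a cohort can legitimately contain patients whose
response "was not determined".

Conventions fixed here, and why:

* **No confirmation scan** is required for PR/CR/PD. Retrospective series
  report best overall response from serial scans; requiring confirmation
  would change BOR for patients who died or switched therapy after a single
  response scan.
* **Non-target lesions** enter only through the new-lesion flag.
  "Unequivocal progression" of non-target disease is a qualitative judgment
  that cannot be recomputed from a diameter table.
* **Nodal short-axis rules are not implemented**; all lesions are treated
  as non-nodal. Hepatic series are dominated by parenchymal lesions, and
  mixing axis conventions without per-lesion axis data would be spurious
  precision.

`derive_pfs()` defines PFS as the time to the earlier of first radiological
progression and death, censored at last follow-up otherwise.
`classify_primary_resistance()` flags initial on-treatment progression, or
progression after stable disease lasting under six months — a best prior
response of PR or better exempts the patient regardless of timing.

## 3. Growth dynamics

Two descriptors quantify how fast disease grows over a time window
\[t₀, t₁\] with burdens S₀, S₁:

* **TGK** (tumor growth kinetics), mm/month: `(S₁ − S₀)/(t₁ − t₀)` — the
  slope of the diameter sum;
* **TGR** (tumor growth rate), %/month: with volume taken proportional to
  the cubed diameter, the log-volume rate is
  `TG = 3·ln(S₁/S₀)/(t₁ − t₀)` and `TGR = 100·(exp(TG) − 1)`.

```{r}
tgr(50, 60, 0, 2)    # +31.45 % tumor volume per month
tgk(50, 60, 0, 2)    # +5 mm of summed diameter per month
```

The volume-calibrated `3·ln(·)` form is the standard definition of a
"log-scale calibrated change in the sum of the volumes"; it is also the
form under which the package's simulator and estimator share one parameter,
making parameter recovery exact (Section 6). TGR is undefined for
nonpositive burdens (log scale); such windows yield `NA` with a warning
rather than an error, so batch runs carry explicit not-evaluable entries.

Fold changes compare a pre-treatment window against an on-treatment
window. `growth_ratios()` returns `NA` with a reason code whenever the
pre-treatment value is not positive: a tumor that was shrinking or static
before therapy has no meaningful "acceleration factor", and silently
coercing those to zero or infinity would bias hyperprogression rates.

**Window convention.** In `assess_hpd()` the pre-treatment window is the
two most recent assessments at or before therapy start — typically a
pre-baseline scan and the baseline itself, whose measurement predates any
treatment effect — and the on-treatment window runs from baseline to the
first progression scan. This matches how case series with a single
pre-baseline scan are evaluated, and uses no data a first-failure analysis
would not have.

**Tumor-burden increase** (TBI) is computed on diameter sums, not volumes:
`100·(S_fail − S₀)/S₀`. "Tumor burden" in RECIST-based criteria
conventionally refers to the diameter sum; a volume convention would
roughly cube the threshold's stringency. This is a genuine ambiguity in
the field's usage; the diameter convention is the package default and the
function is a pure primitive, so a volume variant can be layered on top if
needed.

## 4. The hyperprogression rule

`classify_hpd()` implements the two-criterion rule:

1. time from therapy start to treatment failure **TTF < 2 months**
   (strict); and
2. **first line:** TBI ≥ 50% — **second line:** TGK fold ≥ 2 *and* TGR
   fold ≥ 2 (all inclusive).

Inequality directions follow exactly how the criteria are stated: the TTF
cutoff is strict, the growth criteria inclusive. Boundary behaviour is
pinned by tests (TTF of exactly 2 months is not HPD; TBI of exactly 50% or
folds of exactly 2 are).

Missing inputs propagate as *not-evaluable*, never as "no": a second-line
patient with fast failure but undefined folds (e.g. a shrinking
pre-treatment tumor) gets `NA`. A patient whose treatment never failed is
plainly not hyperprogressive. Thresholds are a `hpd_thresholds()` object,
so alternative HPD definitions from the literature can be explored by
configuration, but the defaults are the rule above.

## 5. Cohort statistics

These stages are standard, and the package deliberately routes them
through the standard implementations (`stats` and `survival`), fixing only
the conventions that change printed numbers:

* **Chi-square** (`chi_square_test()`): Pearson statistic, no continuity
  correction, and — via `contingency_table(na_policy = "category")` —
  missing covariate values form their own category. This pairing is the
  convention under which baseline-characteristics tables with an explicit
  NA row reproduce from their printed counts; the test suite pins six such
  P-values.
* **Fisher** (`fisher_exact()`): the two-sided P sums hypergeometric
  probabilities of all tables (given margins) no more likely than the
  observed one, with a 1e-7 relative tolerance against floating-point
  ties — the dominant software convention. Degenerate margins give P = 1.
  A Monte-Carlo hypergeometric oracle in the tests checks the P-values to
  within three standard errors.
* **Mann–Whitney** (`mann_whitney()`): exact enumeration for untied
  samples of at most 8 per group, otherwise the normal approximation with
  tie and continuity correction.
* **Kaplan–Meier** (`km_fit()`): product-limit estimates with log-log
  confidence intervals. The **median** is read off the curve as the
  earliest event time at which survival reaches 0.5 or less, `NA` when the
  curve never does. (This differs from conventions that average across a
  flat stretch at exactly 0.5; the step-reading rule is unambiguous on
  discrete scan-time data.)
* **Log-rank** (`logrank_test()`): the unweighted statistic with
  df = groups − 1; tests verify it against an independently coded O−E/V
  computation and check P-uniformity under label permutation.
* **Cox** (`cox_fit()`): partial likelihood with Efron tie handling —
  scan-grid PFS times are heavily tied, so the tie method matters — Wald
  CIs and P-values, and the genotype×treatment interaction P as the Wald P
  of the product term. Monotone-likelihood fits (perfect separation in
  small strata, common when all amplified patients progress early) are
  caught and flagged on the object (`glance()$converged`) instead of
  crashing a batch run.

`classify_amp11q13()` reduces the alteration table to a genotype flag:
amplification — not point mutation — of at least one of CCND1, FGF3, FGF4,
FGF19.

## 6. The synthetic cohort

`simulate_cohort()` exists so that the full chain is testable end to end
with known truth. Its defaults are the emulated study conditions, chosen
once:

| Parameter | Default | Meaning |
|---|---|---|
| `n_patients` | 33 | survival-analysis cohort size (20 + 13) |
| `amp_prevalence` | 0.242 | Amp11q13 prevalence |
| `arm_fractions` | 15/33, 5/33, 13/33 | PD-1 first line, PD-1 second line, other therapy |
| `median_pfs_months` | 1.5 / 16.2 / 7.0 / 16.0 | exponential PFS medians by (arm, genotype) |
| `assessment_interval_months` | 42/30.4375 ≈ 1.38 | 6-weekly scans |
| `measurement_rounding_mm` | 1 | whole-millimetre radiology reads |
| `censoring_rate` | 0.2 | fraction censored before progression |
| `hpd_probability` | 0.6 | P(hyperprogressive growth) for amplified PD-1 patients |
| `n_target_lesions_range`, `baseline_diameter_mm_range` | 1–3, 15–70 mm | typical measurable hepatic disease |

Mechanics, and the reasoning behind them:

* **Survival layer.** Event times are exponential with rate ln2/median —
  the simplest law matching a stated median and sufficient for recovery
  testing. Censoring is an independent exponential with rate
  `r·c/(1−c)`, which yields a censoring fraction of `c` exactly under
  competing exponentials and keeps the KM estimand equal to the event-time
  median.
* **Radiology layer.** Each lesion follows
  `D(t) = D(0)·exp(g·t/3)` (volume-exponential growth), with `g` the
  pre-treatment rate before t = 0 and the on-treatment rate after, sampled
  on the scan schedule and rounded. Ordinary progressors get an
  on-treatment `g` *calibrated* so the burden crosses the PD threshold
  (max of +20% and +5 mm) exactly at the drawn progression time — this is
  what ties the two layers together. Designed hyperprogressors get the
  fixed high rate `growth_rates$hyperprogressor` (1.5/month, i.e. tumor
  volume ×4.5 per month), which puts progression at the first scan and
  TBI far above 50%. Censored patients get stable (`0.01`) or shrinking
  (`−0.5`) rates; the stable rate is deliberately below the level that
  could cross +20% within follow-up.
* **Ground truth.** The sidecar `truth` table records each patient's
  rates, true event time and intended-HPD status. Because simulator and
  TGR share the parameter `g`, TGR recomputed from any two unrounded
  on-treatment scans recovers `100·(exp(g)−1)` to floating-point
  precision — the package's sharpest end-to-end invariant.

What the generator does **not** emulate — and therefore what green tests do
not establish about real data: no pseudoprogression or mixed responses
(one growth rate per treatment phase, so no respond-then-relapse
trajectories); no deaths without radiological progression; no inter-lesion
growth heterogeneity within a patient; no measurement error beyond
rounding; scan dates perfectly regular. Real cohorts will also contain
spontaneous fast progressors that satisfy the HPD rule without being
"designed" hyperprogressors — the simulator reproduces this honestly (a
short drawn progression time yields fast calibrated growth), and the test
suite asserts rule-coherence of every call rather than pretending the rule
can separate designed from spontaneous fast growth.

Determinism: a fixed `seed` gives byte-identical tables; the seed is part
of the configuration so a cohort is a pure function of its config.

## 7. Validation problem sizes

The test suite checks, among ~60 properties: KM median recovery within
±20% of the configured median at 500 patients per (arm, genotype) stratum;
Cox log-hazard-ratio recovery within ±20% at n = 500 under a true HR of 5;
Amp11q13 prevalence within 3 percentage points at n = 1000; Fisher
P-values within three Monte-Carlo standard errors of a 10⁵-draw
hypergeometric oracle; and log-rank P-uniformity over 200 label
permutations. These sizes were chosen to make the stochastic checks stable
across seeds while keeping the default suite quick to run.

## 8. Known limitations

* The RECIST engine evaluates targets plus new-lesion flags only; cohorts
  whose progression calls hinge on non-target "unequivocal progression"
  will disagree.
* PFS from simulated radiology is scan-grid-discretized, while the patient
  table carries the exact documented progression date; analyses mixing the
  two will differ by up to one assessment interval.
* The HPD rule is the two-criterion definition; other published
  definitions (TGR fold alone, ΔTGR) are expressible via
  `hpd_thresholds()` and the primitives but are not first-class.
* `cox_fit()` reports monotone-likelihood fits rather than regularizing
  them; small-stratum hazard ratios should be read with their `converged`
  flag.
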