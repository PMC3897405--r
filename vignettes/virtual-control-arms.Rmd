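---
title: "Virtual control arms from nomogram probabilities: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual control arms from nomogram probabilities: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(virtualarm)
```

## The model

A single-arm adjuvant-therapy trial after radical prostatectomy (RP) lacks
an untreated comparator. Post-RP nomograms predict, per patient, the
probability of progression-free survival (PFS) at fixed horizons — here
years 2, 5 and 7, with year 0 pinned at 100%. `virtualarm` turns those four
probabilities into one *virtual PFS time* per patient and uses the
patients' own virtual times as the control arm.

The conversion is threshold inversion: fit a monotone survival curve
$S_i(t)$ through patient $i$'s four points and report the earliest time at
which $S_i(t) \le q$. A single threshold cannot fit every cohort — for a
perfectly calibrated prediction surface the time at $q = 0.5$ matches the
median outcome, while for surfaces that run optimistic (a documented
behaviour of post-RP nomograms in higher-risk populations) more stringent
thresholds compensate. The package therefore carries eight rules,
`model.60` … `model.95` ($q = 0.60, \dots, 0.95$ by $0.05$), targeting
cohorts above median risk, and *learns which rule fits which kind of
cohort*:

* **Reference sets.** On an untreated training cohort, cases are ranked by
  observed PFS — longest first for the moderate-risk class 1
  ($q \le 0.75$), shortest first for the high-risk class 2
  ($q \ge 0.80$); the per-class directions exist because a scan started
  from the wrong end of a modest training set never reaches a chi-square
  nadir. Prefixes of size `seed_size`, …, $N$ are evaluated by the logrank
  chi-square between observed and virtual times within the prefix; the
  minimising prefix is the model's reference set. Prefix ties resolve to
  the smallest (most parsimonious) prefix; prefixes in which either sample
  has no events are skipped and flagged in the scan trace rather than
  failing the scan, since small prefixes of long-PFS cases are often
  event-free.
* **Selection.** A trial cohort is assigned the model whose reference set
  is closest in the weighted Euclidean distance
  $D_m = \sqrt{\sum_{i=1}^{8} w_i (T_i - R_{im})^2}$ over the medians of
  age, margin status, pathologic stage, Gleason primary and secondary
  grades, pre-op PSA, seminal vesicle invasion and nodal status, with
  weights $0.17/0.05/0.17/0.17/0.17/0.17/0.05/0.05$ (continuous variables
  up-weighted). Weights multiply *squared* differences, the standard
  weighted-Euclidean form.
* **Decision.** Observed versus virtual PFS is compared by the logrank
  (Mantel–Haenszel) test on 1 df; chi-square above
  $\chi^2_{0.95,1} = 3.84$ flags disagreement. For censoring-free data the
  Wilcoxon rank-sum test replaces the logrank (exact for groups of at most
  10). The simplified Rubinstein formula
  $\mathrm{power} = \Phi(\sqrt{d}\,|\log \mathrm{HR}|/2 - z_{1-\alpha/2})$
  with $\mathrm{HR} = \log S_b / \log S_a$ and expected events
  $d = n_a(1-S_a) + n_b(1-S_b)$ (complete follow-up; `d` overridable)
  summarises the sensitivity of the comparison. Its survival proportions
  are explicit inputs — they are read off Kaplan–Meier curves by the
  analyst, a step that is deliberately not automated.

### Assumptions

The method assumes the probability tables are a faithful (or at least
rank-preserving) summary of no-therapy risk; that training and trial
cohorts come from comparable populations, so covariate-median proximity is
a proxy for model transferability; and that a single threshold per cohort
is adequate, which holds the better the more heterogeneous the cohort.
The virtual arm is deterministic given the tables — it carries prediction,
not sampling, variability — so the logrank comparison treats a noiseless
arm as if it were a sample; this is inherent to the design.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `method` | `"monotone-cubic"` | — | Fritsch–Carlson monotone Hermite interpolation. `"linear"` doubles as a closed-form oracle; `"loess"` (span 1, degree 1, projected onto the monotone cone) smooths instead of interpolating and is provided for robustness to rounded tables. Local regression through four points is near-degenerate, which is why it is not the default. |
| `horizon_cap` | 15 | years | Extrapolation limit. Beyond year 7 the curve continues at the constant hazard implied by its last segment, $h = \log(S(5)/S(7))/2$; thresholds not reached by the cap yield virtual observations *censored at the cap* — treating them as events would bias the comparison against therapy. |
| `seed_size` | 30 | cases | Starting prefix of the scan; configurable so desk-scale runs (N = 35–50) still scan several prefixes. |
| `w` | 17/5/… % | — | Matching weights; must be non-negative and sum to 1. |
| `normalize` | `TRUE` | — | Min–max scaling of continuous medians by training-pool ranges before the distance. Raw scales would let PSA (~10 ng/mL) dwarf binary variables despite its 17% weight; disable only to replicate raw-scale behaviour. Degenerate training ranges pass through with a warning. |
| Stage coding | pT2→2, pT3→3, pT4→4 | ordinal | Stage enters the distance as a continuous-weighted variable, so a numeric encoding is required; the mapping is a documented convention of this package. |

Medians are ordinary sample medians throughout (even counts average the two
central order statistics), so binary variables can have median 0, 0.5 or 1;
selection ties resolve toward the smaller $q$, whose longer virtual times
are the conservative choice when declaring a therapy benefit.

## Numerical choices

* Non-monotone probability tables (a rounding artifact of web calculators)
  are repaired by antitonic pool-adjacent-violators regression on the four
  points — block means are preserved and already-monotone tables pass
  through unchanged — rather than rejected.
* Threshold inversion brackets the earliest crossing by bisection on
  $[0, \text{cap}]$ down to $10^{-12}$ years, giving $|S(t)-q| \le 10^{-8}$
  wherever $S$ is strictly decreasing; on segments exactly flat at $q$ the
  earliest time is returned. Curves that never reach $q$ by the cap return
  a censored virtual time at the cap.
* Degenerate inputs fail fast with named cases: tables outside $[0,1]$,
  year-0 probabilities different from 1, cohort/panel orphans, samples with
  no events (logrank undefined), survival proportions at 0 or 1 (power
  formula log-undefined).
* Serialisation (reference libraries, trial reports) is plain JSON at full
  double precision; identical inputs produce byte-identical files, and a
  report stores both survival arms so its logrank is recomputable from the
  file alone.

## The synthetic-cohort generator

`simulate_cohort()` emulates a mixed-risk post-RP series: age truncated
normal (65 ± 6 on 45–80), pre-op PSA log-normal (median 10 ng/mL, log-sd
0.6), Gleason grades and stage categorical, adverse-feature rates near
published series (margins ~50%, SVI ~25%, N1 ~15%, ECE ~50%). Outcomes
follow a proportional-hazards Weibull
$S_i(t) = \exp(-(t/\lambda_i)^k)$ whose reference patient (age 65, PSA 10,
Gleason 3+3, pT2, no adverse features) has 95% five-year PFS — the
low-risk prediction level of published post-RP nomograms — with
literature-scale log-hazard ratios (≈0.4–1.0 per adverse feature) and
uniform censoring on 5–15 years (about half the cohort censored, cohort
five-year PFS ≈ 0.70). These values are the generator's fixed defaults,
chosen once for clinical realism.

The probability panel carries $S_i(t)^\gamma$: `miscal_gamma` ≠ 1 emulates
a nomogram that under- or over-estimates relapse risk.
`simulate_null_trial()` draws the *observed* times from the
$\gamma$-distorted law itself (inverse transform), producing cohorts whose
prediction surface is perfectly calibrated to outcomes — the null case for
pipeline calibration checks. `treatment_effect` multiplies event times only
(the tables always describe the untreated course); with the default
exponential baseline a factor of 7 is a hazard-ratio-7 benefit.

What the generator does *not* emulate: surgery-year drift in diagnostic
practice, inter-surgeon variability, non-proportional hazards, informative
censoring, and the discreteness/rounding of real web-calculator output.
Passing tests therefore demonstrate internal correctness and behaviour
under an idealised prediction surface, not performance on real registries.

## Problem sizes in the test suite

The suite exercises: brute-force prefix-scan verification at $N = 40$
(11 prefixes per model, all 8 models); inversion oracles on 1,000 random
tables; permutation checks of the logrank p-value at 6–8 cases per group
(10,000 relabelings); generator law checks at $n = 2000$; and full-pipeline
calibration/detection over 200 replicate cohorts ($n = 150$ null,
$n = 20$ treated) against a 153-case training library. The same quantities
are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Under a *perfectly calibrated* surface the statistically matching
  threshold is $q = 0.5$, which the grid deliberately excludes as below
  median risk; the most lenient grid model then carries a small systematic
  pessimism that a logrank on a large cohort (n ≈ 150) can detect in a
  minority of replicates. The grid's placement presumes the
  optimistic-nomogram setting it was designed for.
* Reference sets depend on the training draw: chi-square-vs-prefix curves
  can show broad minima or multiple nadirs, and modest training cohorts
  yield unstable reference medians, which in turn sways model selection.
  Larger training pools stabilise both.
* The virtual arm has no sampling variability and each virtual time is a
  point summary; per-patient uncertainty in the nomogram output is not
  propagated.
* Only ranked-prefix subsets are searched for reference sets; non-prefix
  subsets are out of scope, as are stratified/weighted logrank variants and
  multi-arm designs.
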