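---
title: "Methods: phenotyping, underestimation, and leakage-guarded prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping, underestimation, and leakage-guarded prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hfgap` quantifies the gap between heart failure (HF) as it exists in a
population and HF as it appears in outpatient claims and death certificates.
This vignette documents the models and procedures, the parameters that
matter, the synthetic-data design, and the numerical choices, in enough
detail that a maintainer could re-derive every default.

## The phenotyping flowcharts

Ambulatory claims carry one ICD-10 code per billed event, entered to justify
the procedure. The ambulatory phenotype is therefore a three-way partition:

- `DIAGNOSED_HF`: at least one event whose code has the 3-character prefix
  I50, dated at the earliest such event;
- `POTENTIAL_HF`: no I50 anywhere in the extraction window, but at least one
  *trigger diagnosis* (I21 acute myocardial infarction, I25 chronic
  ischaemic heart disease, I42 cardiomyopathy, I48 atrial
  fibrillation/flutter) **and** at least one *trigger investigation*
  (BNP/NT-proBNP assay, echocardiography, cardiac catheterisation,
  ergospirometry, Chagas serology);
- `NEITHER` otherwise.

Two readings of the flowchart are defensible — the investigations could
"reinforce" the diagnoses either conjunctively or disjunctively. We adopt
the conjunction as the stricter reading and expose `trigger_logic = "and" |
"or"`; all shipped defaults and tests use `"and"`. Trigger events need not
co-occur on one date: any two qualifying events inside the window count,
because claims impose no visit structure. The classification year is the
year of the earliest *qualifying* event — the first I50 for diagnosed
patients, the first date at which both trigger conditions have been met for
potential patients — and the extraction window includes a 3-year lookback
before the study years so early-window classifications are not biased by
left truncation.

All matching operates on 3-character prefixes (subcodes such as I500 match
their parent I50) because the case definitions cite only 3-character codes.
Code sets support exact prefixes and inclusive lexicographic ranges
(I05–I08); a brute-force range-enumeration oracle backs the matcher in the
tests.

Death certificates list an underlying cause plus the Part I causal chain
(lines A–D) and Part II contributing conditions. A death is `HF_DEATH` if
I50 appears in *any* field including the underlying cause. It is
`POTENTIAL_HF_DEATH` if no I50 appears anywhere and a code from the
mortality search set (B57, I05–I08, I21–I25, I34–I39, I42–I44, I48, I49,
I51) appears on lines A–D or Part II — deliberately excluding the
underlying-cause field, since a death *officially attributed* to, say, I21
with no other cardiac mention is evidence of an infarction death, not of
masked HF. Potential HF deaths are subclassified with a fixed priority when
several sets match: ischaemic (I21–I25) > valvular (I05–I08, I34–I39) >
cardiomyopathy (I42–I44, plus B57 as Chagas cardiomyopathy) > other cardiac
(I48, I49, I51). Ischaemic-first is the only ordering consistent with the
observed predominance (~98%) of infarction/ischaemia among potential HF
deaths; the placement of B57 and of I48/I49/I51 is our decision, as the
three named subclasses do not cover them.

The ambulatory and mortality streams are never linked at patient level; a
patient can legitimately appear in both analyses.

## The underestimation model

Let D be the diagnosed count, P the potential count, and p ∈ [0, 1] the
assumed proportion of potential records that are genuine HF. The combined
true caseload is D + pP, of which official counts capture D, so the
underestimation rate is

U(p) = pP / (D + pP).

U is 0 at p = 0, strictly increasing in p (for D, P > 0), bounded by
P/(D+P), and scale-invariant in (D, P). The published account renders the
equation only as an image; this algebraic form was reconstructed and
verified against all four printed worked values (12% and 35% for the 2018
ambulatory counts at p = 0.2 and 0.8; 41% and 63% for the 2018 death counts
at p = 0.4 and 1.0), which it reproduces exactly after half-up rounding to
whole percent — the package's `round_half_up()`, since banker's rounding
would disagree on exact halves. The "average" scenario values quoted in
prose are ambiguous between per-year values and pooled counts; the grid
emits both (one row per year plus an `ALL_YEARS` row per p using summed
counts) and the tests pin the per-year 2018 values, which match every
printed number.

On synthetic data the identification proportion is observable:
`validate_against_truth()` computes the empirical p̂ (fraction of
POTENTIAL-labelled records that are latently true) and checks that U(D, P,
p̂) equals the brute-force count true-but-uncoded / (coded +
true-but-uncoded) — an exact identity, asserted exactly, not within a
tolerance.

## The synthetic generator

The generator emulates the structure of outpatient billing and mortality
registries: one row per billed event (patient, date, ICD-10 justification,
optional procedure), death certificates with underlying cause + lines A–D +
Part II, and demographics (age ~ N(61, 14.5) truncated to 18–100, ~54%
male, five race categories, height/weight by sex — shaped like the observed
potential-HF population, not an attempt at exact replication).

Its key design choice is the **baseline + excess decomposition**. Every
comorbidity and procedure has a baseline presence probability shared by all
patients (events spread uniformly over the whole extraction window) and an
excess component carried only by true-HF patients, with excess probability
chosen so the marginal presence among true HF equals a logit-shift of the
baseline: planting a log-odds effect b on a feature makes the true
presence odds ratio exactly exp(b), which the tests recover from
contingency tables within Monte-Carlo error. `plant_feature_signal()`
resets all odds ratios to 1 before applying the requested shifts, so a
planted configuration carries signal exactly where stated.

`signal_timing` controls *where* the excess events fall: `"pre"` spreads
them over the pre-diagnostic history; `"washout_only"` confines them to the
365 days before the first I50 code. The second mode exists for the leakage
canary: after washout removal, case and control feature distributions are
identical by construction *except* for observation-window truncation, which
is neutralised by the cohort builder's optional matched pseudo-index for
controls (off by default, since no control index date exists in the study
design). Under that configuration the held-out AUC must be statistically
indistinguishable from 0.5; moving the same signal before the boundary must
make it clearly learnable (AUC > 0.7 in the tests at 20 000 patients).

Other generator mechanics: per-patient event counts are Poisson (no
generative model is prescribed by the source; Poisson is the simplest
analytically checkable choice); HF onset is uniform over the study window;
the first I50 date is onset plus a uniform 0–24-month investigation delay,
capped at the window end so a coding probability of 1 guarantees an I50
event in-window; deaths follow an annual hazard multiplied (default 4×)
among true HF; an HF death is *masked* with configurable probability, in
which case an ischaemic-heavy mortality-set code (59% I21, 39% I25, the
rest spread thinly — reproducing the ~98% ischaemic share) is written to
line A and the underlying cause with no I50 anywhere; unmasked HF deaths
carry I50 in the underlying cause (60%) or on a line (40%). Non-HF deaths
draw non-cardiac causes but carry a mortality-set code on a line with
probability 0.15 (`nonhf_trigger_death_rate`) — fatal infarctions without
HF exist, and without them the empirical p̂ would be trivially 1.
Demographic missingness is completely at random per field (the pipeline
handles missingness by exclusion and imputation, not by modelling its
mechanism).

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: regional and facility structure,
care-seeking behaviour, coding-practice drift over time, the COVID-era
disruption visible in real 2020 counts, correlated comorbidity clusters,
and informative missingness. Tests against this generator validate the
*machinery* (labels recover planted truth; the washout blocks in-window
signal), not real-world model performance.

## Cohort construction and leakage control

Modelling cohorts are built in this order:

1. **Completeness filter**: patients missing any of age, sex, weight,
   height, race are excluded (these fields define eligibility).
2. **Washout**: for cases, only events dated `event_date <= first_i50_date
   − 365` days are kept — calendar-day arithmetic, inclusive boundary, no
   leap-year special-casing, the simplest auditable reading of "at least 12
   months prior". No events from the labelling year (2022 by default) are
   used for anyone; features come from 2018–2021. Cases whose entire
   history falls inside the washout are retained with all-zero counts and
   flagged. `assert_no_leakage()` machine-checks both constraints.
3. **Features**: untransformed event counts per 3-character prefix and per
   ICD-10 chapter (a static letter-range table; codes outside every range
   bucket to `OTHER`), procedure counts, and demographics.
4. **Plausibility**: age outside 18–110 years or BMI outside 12–60 kg/m²
   drops the patient (eligibility violations); count features above the
   *training* 99th percentile are set missing and median-imputed rather
   than dropping the patient (record-level treatment of probable data-entry
   errors; a switch restores patient-level dropping, since either reading
   of "removed from further analysis" is defensible).
5. **Preprocessing**: training-partition medians (continuous) and modes
   (categorical) for imputation; one-hot encoding against training levels;
   standardization only on the linear-model path. The state is a value
   object serialisable to JSON; model code takes a preprocessor *factory*
   so every cross-validation fold refits its own state — the no-leakage
   contract is structural, not conventional.
6. **Cohorts**: a balanced development cohort (default 10 000 cases +
   9 995 controls, the study's sizes), independent validation cohorts
   (20 000 and 17 041), and a low-prevalence evaluation set (175 cases
   among 8 716, ~2%). All four sets are pairwise disjoint by patient id —
   the low-prevalence set is drawn from the remaining pool rather than from
   inside a validation cohort, trading fidelity to the original sampling
   description for an unambiguous non-overlap guarantee. An 80/20
   stratified split is drawn inside the development cohort. Controls have
   no index date, so their features use the full 2018–2021 window; the
   matched pseudo-index option (above) exists for bias exploration only.

## Risk models and the two-stage search

The gradient-boosting learner is delegated to xgboost's histogram method
behind a thin interface; the hyperparameters keep their conventional names
and map directly (depth → `max_depth`, learning_rate → `eta`, iterations →
`nrounds`, l2_leaf_reg → `lambda`, border_count → `max_bin`). The default
spec ships the tuned values reported for the study model (learning_rate
0.083, l2_leaf_reg 25, iterations 900, depth 8, border_count 30) as a named
preset — a structural reference point, not a claim that those values are
optimal on other data. The baseline is L2-penalised logistic regression
(ridge, fixed small penalty) with class-balanced weights n/(2·n_class) and
standardized predictors; constant features are dropped with a warning.

Cross-validation is stratified 5-fold (label ratio within one count per
fold), with no rebalancing or resampling inside folds. The hyperparameter
search runs in two stages: stage 1 samples uniformly from the broad space
(depth 1–10, learning_rate 0.01–1, iterations 100–1000, l2_leaf_reg 2–100,
border_count 10–35); stage 2 refines inside the narrowed space (depth 5–10
integer, learning_rate 0.01–0.5 log-uniform, iterations 500–1000 integer,
l2_leaf_reg 2–35 log-uniform, border_count 10–35 integer), warm-started
from the full stage-1 trace: each iteration fits a random-forest surrogate
to the (configuration → mean CV AUC) trace and evaluates the
best-predicted candidate from a fresh random pool. A tree-ensemble
surrogate over a mixed integer/log-scale space is robust without kernel
tuning; the random candidate pool supplies the exploration that a pure
argmax lacks. Decision threshold for confusion matrices defaults to 0.5 and
is an argument everywhere.

All randomness flows from explicit integer seeds; stage seeds are derived
from one global seed by a fixed hash, and identical configurations are
byte-identical end to end (xgboost runs single-threaded).

## Evaluation metrics: formulas and numerical choices

- **AUC**: Mann–Whitney rank form with average ranks, so ties count one
  half; equals the O(n²) pairwise-concordance oracle on every tested
  instance and an independent ROC implementation on larger ones.
- **Confusion rates**: rates with zero denominators are reported as `NA`,
  never as zero — on a 2%-prevalence set an all-negative classifier shows
  accuracy 0.98 with recall 0, the "accuracy trap" the low-prevalence
  evaluation is designed to expose.
- **Brier**: mean squared error of probabilities; matches the closed form
  p²(1−π) + (1−p)²π for constant predictors.
- **ECE/MCE**: default 10 equal-width bins (quantile binning by flag; the
  scheme is recorded in every report); empty bins are skipped; ECE ≤ MCE by
  construction.
- **Calibration slope/intercept**: maximum-likelihood logistic fit of
  outcomes on logit-transformed predictions, scores clipped to
  [10⁻⁶, 1−10⁻⁶] so degenerate scores stay finite; all-identical scores are
  an error, not a silent fit. Calibration-in-the-large (intercept with
  slope fixed at 1) is reported alongside. Under sampling labels ~
  Bernoulli(score) the fit recovers (1, 0) within ±0.05 at n = 50 000.
- **Hosmer–Lemeshow**: grouped Pearson statistic over score-quantile
  deciles (ties kept together; groups with expected counts of 0 or n merged
  into a neighbour). Degrees of freedom are g − 2 by default, the standard
  choice when the probabilities were fitted on the same data. When the
  probabilities are *externally supplied* — a validation sample scored by a
  model fitted elsewhere, which is also the design of our size simulation —
  the statistic is approximately χ²(g) (the D'Agostino–Nam convention), and
  `external = TRUE` selects that reference. The distinction is not
  pedantic: with df = g − 2 the external-probability simulation rejects at
  ~11% instead of 5%. The tests verify nominal size (rejection rate within
  [0.02, 0.09] at α = 0.05 over 500 replicates of n = 10 000) under the
  external reference, and the package reproduces the familiar pattern that
  at very large n the HL test flags deviations that ECE shows to be tiny.
- **Permutation importance** is the native attribution method (mean AUC
  drop over repeated single-feature shuffles); Shapley-value explainers are
  deliberately out of scope.

## Problem sizes and limitations

The test suite exercises the generator at 20 000–30 000 patients for
rate-recovery checks (99% binomial CIs), 20 000 patients for the leakage
canary, 100 000 for cohort assembly at the study's exact sizes, and smaller
populations elsewhere; these sizes make every Monte-Carlo band comfortably
wider than simulation error while keeping the default run fast on one CPU.

Known limitations: the flowchart topology beyond the conjunction rule is a
declared reading, not a reconstruction of the original figure; "absence of
I50" is evaluated over the study window plus lookback, not over a
patient's lifetime; the published model-performance figures (AUC ≈ 0.91 on
registry data) are not reproducible without the registry microdata and are
not targets of this package — the modelling stack is validated by
property-based checks and planted-signal recovery instead; and the
deterministic sensitivity analysis is exactly that — deterministic — so no
confidence intervals accompany U(p).
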