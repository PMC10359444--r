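---
title: "Stratified association rules for kidney outcomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified association rules for kidney outcomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

dkdrules implements a transparent risk-communication analysis for diabetic
kidney disease: instead of odds or hazard ratios, it reports
single-antecedent **association rules** between the state of a routine
health-examination risk factor and the five-year kidney outcome, within
clinically meaningful strata.

For each factor X and stratum, two rules are evaluated:

* *absence of X → stable kidney function*, with
  `confidence_stable = n(absent & stable) / n(absent)`;
* *presence of X → worsening kidney function*, with
  `confidence_worsening = n(present & worsening) / n(present)`.

Confidence is the empirical conditional probability of the outcome given
the factor state. **Lift** divides the confidence by the outcome's
marginal rate in the same stratum,
`lift = confidence / (n(outcome) / n(all))`, and a rule is called
significant when lift is strictly greater than 1 — i.e. the factor state
carries information beyond the stratum's base rate. Lift exactly 1 is not
significant, and an empty antecedent yields an undefined (not zero)
confidence: 0/0 is absence of evidence, not evidence of absence. No
multiple-testing correction is applied; the lift rule is deliberately the
whole inferential apparatus, keeping the output interpretable at the cost
of uncontrolled error rates (a limitation users should weigh).

### Outcome definition

Worsening kidney function is a ≥ 30% decrease in eGFR from baseline at
*any* follow-up within the five-year window (a validated surrogate for
end-stage kidney disease); in worker cohorts an ESKD diagnosis, dialysis
initiation or kidney transplant also qualifies. Stable kidney function is
the complement. eGFR comes from the Japanese serum-creatinine equation
`194 · Cr^-1.094 · age^-0.287 (· 0.739 if female)`. We evaluate the −30%
crossing at single follow-ups without requiring confirmation at a second
visit, because the outcome window is short and examinations are annual;
sustained-decline definitions would need denser sampling. The boundary
case (exactly −30%) counts as worsening. Percent changes are computed on
full-precision eGFR values — no intermediate rounding — so threshold
artifacts at the boundary cannot arise from the pipeline itself.

### Eligibility and baseline

Subjects enter the analysis when they meet the diabetes definition
(HbA1c ≥ 6.5%, fasting glucose ≥ 7.0 mmol/L, or treated diabetes; missing
criteria count as not met), have a baseline, and have at least one
creatinine-bearing follow-up inside the window. Baseline is the earliest
creatinine-bearing visit from which the subject is still observed for at
least `followup_years` (default 5). Two points were genuinely open and
are resolved as follows:

* **Diabetes is anchored at baseline**, falling back to the most recent
  earlier visit when the baseline labs are missing. A subject who becomes
  diabetic only after baseline is excluded; all risk factors are baseline
  quantities, so status should be too.
* **"Followed for at least five years"** is read as last-visit span ≥ 5
  years from baseline; visits after `baseline + followup_years` are
  ignored entirely, closing the outcome window at exactly five years.

Exclusion reasons are attributed first-failing-rule-wins in the order
not diabetic → no baseline eGFR → insufficient follow-up. The order
affects only the bookkeeping, never the final cohort (a property the test
suite checks against an independent re-screening).

### Risk-factor binarization

Continuous factors are dichotomized at **sex-specific percentile
thresholds** computed on the analysis cohort at baseline, before any
stratification: the upper 20% is "risk" for factors where high values are
adverse (HbA1c, fasting glucose, liver enzymes, lipids other than HDL,
blood pressure, BMI) and the lower 20% for eGFR, hemoglobin (anemia) and
HDL. The sensitivity setting uses 10% tails. Quantiles use linear
interpolation between order statistics (`stats::quantile()` type 7);
presence requires *strict* exceedance, so a value exactly at the
threshold is absent. With tie-free data this flags exactly ⌊n·p⌋/n of
each sex. Dipstick proteinuria is categorical: negative/trace vs ≥ 1+.
Missing analytes produce missing flags and are excluded from that
factor's rules only (per-factor complete case), which preserves each
formula's denominators; listwise deletion would couple unrelated
factors' missingness. Percentile thresholds are population-relative, not
clinically anchored cut-offs — a deliberate, uniform choice that is also
the approach's main clinical limitation.

### Stratification

Rules are mined overall and within strata defined by (1) modified KDIGO
CKD risk categories, (2) diabetic retinopathy, and (3) the two-year eGFR
change, in the nested schemes (1), (1)×(2), and (1)×(2)×(3) (with the
four risk categories collapsed to low/moderate vs high/very-high when
crossed). The KDIGO grid is modified by replacing albuminuria with
dichotomized dipstick proteinuria: negative/trace follows the A1 column
(G1/G2 low, G3a moderate, G3b high, G4/G5 very high) and ≥ 1+ follows A2
(G1/G2 moderate, G3a high, G3b–G5 very high). Whether ≥ 1+ should map to
A2 or A3 for preserved GFR cannot be settled from dipstick data alone;
the grid is therefore an explicit, overridable argument
(`ckd_risk_map()`), and the default is documented as an assumption. The
two-year change uses the follow-up nearest to baseline + 2 years within
±1 year (ties to the earlier visit), since annual examinations rarely
fall exactly on the anniversary. Subjects missing a stratifier drop out
of the schemes that need it and remain in all others.

A structural consequence worth noting: any subject in the "< −30% at two
years" stratum has already met the worsening definition, so no stable
outcomes can occur there — the stable-rule cells of that stratum are
undefined by construction, not by data sparsity.

## The synthetic cohort generator

The cohorts this analysis was designed for are private health-examination
registries; the package therefore ships a generator that reproduces the
*statistical structure* the analysis depends on, so every stage is
testable against known ground truth.

* **Marginals.** Baseline labs are drawn from lognormal distributions
  moment-matched to each analyte's mean ± SD (defaults: mean age 66.7 ±
  7.7, HbA1c 7.4 ± 1.3%, eGFR 75.0 ± 18.3, GGT 50.2 ± 67.4, … for the
  general profile; a younger, mostly male worker profile with its own
  values). The lognormal was chosen over a zero-truncated normal because
  it matches the requested mean and SD *exactly* while staying positive —
  a truncated normal cannot for high-CV analytes like GGT, where
  truncation would inflate the mean by ~26 IU/L — and because
  right-skewed lognormal shapes are the textbook description of these
  labs.
* **Latent risk states.** Each subject first receives a binary latent
  state per factor (probability 0.2, matching the 20% analysis tail;
  proteinuria and retinopathy use their own prevalences, 11.6%/29.1% and
  20%/15% for the two profiles), then the analyte is sampled from the
  corresponding tail or body of its marginal in quantile space. The
  mixture marginal is exactly the lognormal, and downstream percentile
  binarization re-identifies the latent state with accuracy well above
  0.9 (verified in tests), making binarization testable against truth.
* **Outcome mechanism.** The worsening probability is
  `base_rate × ∏ RR_f` over present factors, capped at 1. Worsening
  subjects follow a linear eGFR decline crossing −30% at a uniform random
  time in [1, 5] years and continuing at that slope; stable subjects keep
  baseline creatinine up to i.i.d. ±3% measurement noise (their eGFR
  still drifts down ~2% over five years through the age term — far from
  the −30% boundary, so the realized outcome equals the latent assignment
  essentially surely). This is the simplest mechanism that makes both the
  five-year outcome and the two-year slope strata non-degenerate.
* **Calibration.** The marginal worsening rate implied by a base rate and
  effect map is computed exactly by enumerating the 2^k states of the
  k factors with non-unit RR (`expected_worsening_rate()`), and
  `calibrate_worsening_rate()` inverts it with `uniroot()`. The ready-made
  profiles calibrate to five-year worsening fractions of 4.8% (general)
  and 5.1% (worker). The default effect map (glycemia RR 2.2–2.5,
  proteinuria 2.4, anemia 1.8, reduced eGFR 1.6, blood pressure 1.5,
  obesity 1.4, triglyceride/HDL 1.3) is a qualitative convention — chosen
  once to make glycemic and proteinuric factors the strongest signals,
  consistent with clinical expectation — not an estimate from any cohort.
  `designed_worsening_probability()` exposes the exact conditional
  P(worsen | factor state) for parameter-recovery checks.

**What the generator does not emulate:** physiological correlation
between analytes (each is drawn independently given its latent state),
treatment effects, mortality or censoring, within-subject lab drift
beyond small noise, and non-random missingness (only
missing-at-random retinopathy is available). Passing tests on synthetic
data therefore demonstrate that the pipeline computes the intended
quantities under the designed dependence structure — not that any
particular real-world association holds, nor that the analysis is robust
to correlated confounding, which single-antecedent rules by construction
do not adjust for.

## Numerical and degenerate-input conventions

* Undefined confidence/lift propagate as `NA` and render as blank cells;
  grayed cells are defined-but-not-significant (lift ≤ 1).
* Empty strata produce all-zero counts, not errors; the mined table is
  always the complete scheme × stratum × factor × rule cross-product in
  a bit-stable order, so repeated runs are byte-identical.
* Constant-valued factors flag nobody (no strict exceedance).
* A single-subject cohort reports SD as `NA` by default
  (`baseline_table(..., sd_single = "zero")` opts into 0).
* Stored creatinine is rounded to 4 decimals and other labs to 2, so
  CSV round-trips are exact while keeping values lab-realistic.

## Problem sizes used by the test suite

The suite exercises: exact oracle equivalence against a brute-force
row-loop on 200 random tables of ≤ 20 rows; parameter recovery on one
20,000-subject cohort with a designed HbA1c relative risk of 3; null
calibration over 200 replicate cohorts of 2,000 subjects (the fraction of
factors with lift > 1 hovers around ½ under independence); threshold
behavior on 1,000 tie-free values per sex; and byte-level determinism of
the full pipeline at 800 subjects. These sizes give the statistical
checks 3-SE (binomial) resolution while keeping a full run of the suite
around four minutes on a single core.

## Known limitations

Beyond those noted above: confidences are raw conditional frequencies
with no uncertainty intervals in the default output; strata with few
events produce volatile lifts (the null-calibration test quantifies how
volatile); the KDIGO-grid mapping for dipstick data is an assumption;
and the eligibility rules assume annual-examination data — irregular
visit schedules will interact with the ±1-year two-year window and the
five-year span rule in ways the defaults may not anticipate.
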