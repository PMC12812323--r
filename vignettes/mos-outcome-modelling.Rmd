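---
title: "Medication optimization scoring and its longitudinal outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Medication optimization scoring and its longitudinal outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Guideline-directed medical therapy (GDMT) for heart failure with reduced
ejection fraction (HFrEF) rests on four drug classes — a renin-angiotensin
system inhibitor (ACEI, ARB or ARNI), a beta-blocker, a mineralocorticoid
receptor antagonist and an SGLT2 inhibitor — each with a guideline target
daily dose. In routine care most patients sit well below those targets.
`hfmos` implements a computable medication optimization score (MOS) that
summarises, per patient encounter, how close the regimen is to full
guideline optimization, together with the statistical machinery needed to
relate that score (and its change over time) to death and hospitalization
in an ambulatory cohort.

## The scoring model

Each GDMT class contributes one possible point; the earned share is the
continuous fraction of the target daily dose, `min(dose / target, 1)`:

\[
\mathrm{MOS} = 100 \times
 \frac{\sum_{c \in \mathcal{E}} \min(d_c / t_c, 1)}{|\mathcal{E}|},
\]

where the denominator set \(\mathcal{E}\) contains only classes the patient
can actually receive. Three eligibility mechanisms shape it:

* **Intolerance / allergy** — a documented class intolerance removes the
  class from numerator and denominator, so the score is not deflated by
  medication the patient cannot take (and not inflated by pretending the
  class was optimized).
* **Contraindication rules** — vitals/lab thresholds (defaults: MRA blocked
  at K+ > 5.0 mmol/L or eGFR < 30; SGLT2i at eGFR < 20; RASI at K+ > 5.5 or
  SBP < 90 mmHg; beta-blocker at pulse < 55 bpm) likewise remove the class.
* **Escalation blocks** — a class prescribed below target whose
  up-titration is blocked (SBP < 95 mmHg for RASI/beta-blocker, pulse < 60
  for beta-blocker) earns full credit at its current dose.

A missing vital or lab is handled conservatively: a rule that cannot be
evaluated does not fire, and the result carries an annotation. If every
class is excluded the score is undefined and flagged, never silently 0 or
100. The same regimen classification feeds three comparator scores: the
Heart Failure Collaboratory score (0-7; 0/1/2 points at the 50% threshold
for beta-blocker and ACEI/ARB, 2 for any MRA dose, 3 for any ARNI dose,
contraindicated classes graded at their slot maximum), its modification
(0-8; every slot on the 0/1/2 scheme with the ARNI split into sacubitril
and valsartan components, rescaled to 0-100 by dividing by 8), and the
Kansas City Medical Optimization score (mean prescribed-to-target fraction
over eligible classes with a binary MRA).

The per-class point weights, the formulary (drugs, targets, titration
ladders) and every eligibility threshold live in YAML configuration
(`inst/extdata/`); the defaults are guideline target doses and standard
safety thresholds, with equal class weights preserving the printed 0-100
semantics. The 50% threshold in the comparator scores is closed
(`>= 0.5`).

Two risk indices accompany the score. The Charlson Comorbidity Index ships
with the original seventeen condition-group weights and hierarchical pairs,
graded mild (1-2), moderate (3-4) and severe (>= 5); a score of zero falls
below the published grade boundaries and is binned with mild, annotated.
The heart-failure severity index (HFPSI, ordinal 1-4) is computed from six
components (BUN, BNP, NYHA class, diabetes, AF/flutter history, recent
hospitalization) through a configurable monotone integer map; because the
published integer weighting of its source model is not reproduced here, the
packaged map is an explicit stand-in (quartile-style points on BUN and BNP
plus one point per binary component, cut onto 1-4) and any monotone map can
be supplied. In the synthetic-data recovery experiments HFPSI is therefore
*generated* directly as an ordinal state rather than derived.

## The outcome models

Encounters are grouped into 182-day (6-month) intervals indexed from 0
(baseline) to 7, i.e. out to 42 months; the interval width and maximum are
configurable. Exposure construction follows three rules: the per-interval
exposure is the arithmetic mean of the encounter-level MOS in the interval;
intervals without encounters carry the last observed mean forward (the
cumulative exposure is unaffected because it averages raw encounters); and
the time-varying exposure of the cumulative model is the one-interval-lagged
cumulative mean — all encounter-level values strictly before the interval's
start day — so no exposure value uses information from its own interval
(tested by a masking audit). Follow-up is expanded into half-open
counting-process rows `[182k, min(182(k+1), T))`.

Four models are fitted:

* **A** — unadjusted Cox on the baseline MOS per 10 units;
* **B** — A plus age per 10 years, sex, race, ethnicity, HFPSI (reference
  level 1) and CCI grade (reference mild), model-based SEs;
* **C** — time-varying Cox on the lagged cumulative MOS per 10 units plus
  the baseline covariates, patient-clustered robust SEs;
* **D** — the marginal structural Cox model below.

Kaplan-Meier curves (Greenwood variance, log-log CI) and the log-rank test
compare baseline MOS tertiles cut at the empirical 33rd and 67th
percentiles (linear-interpolation definition; ties go to the lower
tertile). Efron tie handling is the Cox default because day-granular data
produce ties; the weighted-equals-duplicated-rows oracle check uses
Breslow, for which that equivalence is exact.

### The marginal structural model

Severity both responds to therapy and drives further titration, so a
time-varying Cox adjusted for severity would condition away part of the
treatment effect, while ignoring severity confounds it — the classic
treatment-confounder feedback situation. Model D therefore weights each
patient-interval by stabilized inverse-probability weights. For the
continuous exposure, the treatment weight is a ratio of conditional
Gaussian densities from two linear exposure models: the numerator
conditions on prior MOS, baseline covariates (age, sex, race, ethnicity)
and time (a categorical interval indicator, avoiding a linearity
assumption on baseline drift); the denominator additionally conditions on
the one-interval-lagged HFPSI and CCI. Homoscedastic residual SDs define
the densities — the standard linear-Gaussian construction for continuous
exposures. Censoring weights come from pooled logistic models of remaining
free of loss to follow-up, with baseline distance from the treating center
in both numerator and denominator; administrative end-of-study censoring
is deterministic and not modelled. Cumulative weights are running products
over intervals within patient (interval 0 has weight 1 — no prior exposure
exists to model), each weight family is winsorized at its own pooled
1st/99th percentiles *before* multiplication (a switch truncates the
product instead), and the weighted Cox uses the current-interval MOS per
10 units with patient-clustered robust SEs. Because the stabilized
numerator conditions on the baseline covariates, the weighted outcome
model adjusts for them as well; omitting them would attenuate the estimate
through non-collapsibility of the hazard ratio.

Design choices taken where the construction was genuinely open: truncation
percentiles are computed pooled over all rows rather than per interval;
time enters the weight models categorically; the exposure for interval 0
is the baseline MOS itself.

### The trend model

Score trajectories are modelled as
\(\mathrm{MOS}_{it} = \beta_0 + \beta_1 t + b_{0i} + b_{1i} t +
\varepsilon_{it}\) with bivariate-normal random intercepts and slopes, time
in 6-month interval units (one "quarter" of the follow-up structure —
the interval index, not a calendar quarter, since that matches the panel;
the unit is configurable). REML estimates are reported; the random-slope
likelihood-ratio test refits both models by ML and, because the null slope
variance sits on the parameter-space boundary, refers the statistic to the
50:50 mixture of chi-square(1) and chi-square(2). A singular random-effects
covariance triggers a refit with the correlation fixed at zero, flagged in
the result.

## The synthetic cohort generator

No patient-level data accompany the package; the generator supplies
cohorts with *known causal truth* so every estimator can be tested by
parameter recovery. Its defaults are the study conditions the analyses
assume, fixed once:

* baseline MOS ~ N(56, 21) clipped to [0, 100] (clipping is the score
  domain, and the point mass at 100 exercises the fully-optimized
  exclusion); baseline HFPSI marginals 46.4/23.0/18.5/12.1%, CCI grades
  19.9/21.0/59.1%; age 64.7 +/- 14.3, 65% male;
* titration: mean gain 3.3 percentage points per interval at the lowest
  severity, patient-level slope SD 2, within-patient noise SD 6 pp;
  lagged severity slows titration by 2.5 pp per level above 1
  (`feedback_hfpsi_on_mos`), so the realised population trend is shallower
  than 3.3 pp — the generator's trend parameter is severity-conditional;
* severity transitions: an ordinal latent-perturbation step shifted by
  lagged MOS (`feedback_mos_on_hfpsi` = -0.05 per 10 units), closing the
  treatment-confounder feedback loop;
* hazard per interval: `0.015 * exp(log(0.88) * MOS/10 + beta_hfpsi[HFPSI]
  + beta_cci[CCI] + log(1.4) * age/10)` with severity/comorbidity hazard
  ratios (1.5, 1.65, 3.0; 1.2, 2.5) of the magnitude reported for such
  cohorts; event days uniform within the interval (discrete-time hazard
  with exact-day placement, since the analyses consume counting-process
  rows rather than continuous event times);
* censoring: per-interval logistic with baseline log-odds logit(0.04) and
  +0.5 per 100 km of distance from the center.

Two fidelity levels share these dynamics. The score-level generator emits
the MOS panel directly and is what the recovery experiments use. The
medication-level generator additionally realises each latent score as a
concrete regimen by inverting the MOS formula (classes fill to target in a
fixed order; the remainder class carries the fractional dose), re-stating
the full regimen at every encounter (zero-dose rows discontinue drugs
under carry-forward scoring), and drawing vitals and labs around typical
ambulatory HFrEF values. Vitals are truncated to eligibility-safe ranges
(SBP >= 100, pulse >= 62, K+ <= 4.9, eGFR >= 32) so that no
contraindication or escalation rule fires on synthetic encounters: the
generator emulates dose titration, not contraindication dynamics, and this
is what makes the medication-level tables round-trip through the scoring
engine to the latent trajectory within +/-1 score point. Consequently the
synthetic data do not exercise intolerance-driven denominator changes,
realistic pharmacokinetics, adherence, or competing risks — passing
recovery tests show the estimators work when their assumptions hold, not
that those assumptions hold in any real cohort.

A deliberately unclipped companion generator (`simulate_lmm_data()`)
produces pure linear-mixed-model trajectories for validating the trend
model: with an intercept near 61 pp the clipped score-domain generator
would truncate trajectories at 100 and bias slope recovery, so the trend
oracle needs data actually generated from the LMM.

## Numerical choices and problem sizes

Interval width is exactly 182 days for reproducible integer arithmetic.
Tertile cuts use the type-7 interpolated quantile. The Cox oracle tests
compare against a one-dimensional brute-force partial-likelihood search on
datasets of up to 8 subjects, to 1e-4. The packaged experiments run at the
sizes the validation suite uses — naive-versus-MSM recovery over 25
replicates of 2000 patients, null-coverage over 50 replicates of 1000, LMM
recovery at 1000 patients over 6 intervals — sizes at which Monte-Carlo
error is small relative to the effects being recovered. Under the default
feedback strengths the severity-omitting naive time-varying Cox
overstates the protective effect (mean bias about -0.03 on the log scale)
while the MSM's residual bias is several-fold smaller; the replicate
experiments in the test suite compute these quantities afresh on every
run.

## Known limitations

The MOS point weights and eligibility thresholds are configurable defaults,
not the proprietary rule tables of any deployed decision-support system;
the HFPSI map is a monotone stand-in; the generator's severity process is a
four-state ordinal walk rather than a clinically calibrated progression
model; and the MSM assumes correctly specified linear-Gaussian exposure
densities — under gross misspecification (heteroscedastic or multimodal
exposure) the weights lose their mean-one stabilization property, which
`build_msm_weights()` makes auditable by returning every contribution.
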