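---
title: "Emulating a trial of hearing-aid use and dementia risk: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a trial of hearing-aid use and dementia risk: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatrial)
```

# The estimand and the emulated trial

`hatrial` estimates the effect of initiating hearing-aid (HA) use, in
adults with incident hearing loss (HL), on the risk of a recorded dementia
diagnosis, using the target-trial-emulation framework on observational
cohort data with linked electronic health records (EHR).

The emulated protocol is:

* **Eligibility** — any indication of HL from self-report, a
  speech-in-noise (SiN) test, or the EHR, with no dementia record, no HA
  use and no cochlear implant at or before the HL date, HL not ascertained
  before the participant's entry assessment, and enough follow-up left for
  a full grace period.
* **Time zero** — the earliest HL record across sources.
* **Treatment strategies** — initiate HA within one year of time zero and
  sustain it, versus never initiate.
* **Assignment** — by compatibility of the observed data with each
  strategy within the one-year grace period; randomization is emulated by
  adjusting for baseline confounders.
* **Follow-up** — from time zero to dementia, death, or administrative end
  of records; the per-protocol analogue additionally censors controls at
  late HA initiation and HA users at recorded cessation.
* **Contrasts** — observational analogues of intention-to-treat and
  per-protocol effects, reported as marginal risk ratios in the treated
  (ATT) and as hazard ratios.

The estimand is fixed to the ATT — the effect among HA initiators — both in
the weighting and in the g-computation standardization. The source cohort
never names its estimand; the ATT is this package's documented choice (the
weighting scheme the balance step prefers is ATT-shaped), and `estimand =
"ATE"` is available throughout.

## Ascertainment rules

HL is ascertained per source and dated at the earliest available record:

* *Self-report*: two paired questions (hearing difficulty; hearing
  difficulty with background noise). Both must be answered "yes" at the
  same visit. One "yes" with the other unanswered makes the self-report
  source **missing**, not negative. "Do not know" and "prefer not to
  answer" are missing by convention.
* *SiN test*: the speech-reception threshold in noise, in dB; higher values
  mean poorer hearing. Thresholds at or above **−5.5** classify HL.
* *EHR*: the first HL-class code; if codes exist but all lack dates the
  source is missing.

Same-month ties are attributed ehr > sin_test > self_report. The tie order
is arbitrary (no convention exists for it) and fixed so that ledger counts
are reproducible.

HA use is dated at the earliest of self-reported use at a visit and EHR HA
codes; cochlear-implant records are tracked separately and make a
participant ineligible when dated at or before time zero (implant users
cannot take the SiN test, so their confounders are incomparable).

## Boundary conventions

All dates are handled at month precision (age is computed from month and
year of birth). "Outcome before HL" excludes dementia dated at **or
before** the HL month, so every retained outcome event falls strictly
inside (time zero, follow-up end]. "HL before baseline" means a strictly
earlier month than the entry assessment. Hospital-use categories are
left-open/right-closed above zero with 0 its own category (0, (0,0.2],
(0.2,0.5], >0.5 mean annual spells); primary-care categories are [0,12],
(12,24], >24 mean annual events, the lowest closed at both ends — matching
the printed labels. Exclusion reasons follow a fixed cascade order, so each
participant carries exactly one reason and the ledger is reproducible.

One eligibility rule is an addition this package makes explicit: time zero
must leave a **full grace period before the administrative end of
follow-up**. Without it, arm classification is truncated differentially by
entry date (a late entrant's HA initiation can fall outside EHR coverage),
which acts as a structural confounder that no baseline covariate captures.

## Estimation

**Doubly robust risk ratio.** A weighted logistic outcome model
(`event ~ arm + covariates`, weights from the selected adjustment) is
standardized over the treated rows: predicted risks are averaged with arm
set to HA and to control, and the ratio is reported. The estimator is
doubly robust in the usual sense: consistent if either the propensity model
behind the weights or the outcome regression is correctly specified. The
variance stacks the outcome-model score with the two standardization means
in one M-estimation sandwich and applies the delta method to the log risk
ratio, treating the weights as fixed; the extra uncertainty from propensity
estimation is acknowledged and covered by the bootstrap mode
(`se_method = "bootstrap"`), which refits propensity, weights and outcome
model per resample. 95% intervals use the fixed 1.96 multiplier. An
`interactions = TRUE` switch adds treatment–covariate interactions, the
saturated g-computation form under which, for fully categorical covariates,
the standardized risks coincide with direct cell enumeration.

Two numerical accommodations for sparse strata: an outcome-model column
whose coefficient runs away (|log-odds| > 15, the signature of a factor
level with no events) is dropped and the model refitted, and if the
sandwich system is still numerically singular it is inverted in its
informative subspace via the SVD. Similarly, the propensity model tolerates
isolated structural zeros (clamped scores; those rows' ATT weights vanish)
and errors only on genuine separation (>2% of fitted values at the bounds,
or non-convergence).

**Survival analyses.** Inverse-probability-weighted Kaplan–Meier curves
(weighted risk sets and event counts; discarded rows leave the risk set)
and weighted Cox models with robust score-residual standard errors and the
Efron tie correction, both through the survival package. Follow-up times
get a half-month floor, the smallest distinguishable interval at month
precision.

**Balance and selection.** SMDs use the pooled pre-adjustment SD as a fixed
denominator so methods stay comparable; variance ratios and weighted
Kolmogorov–Smirnov statistics complete the per-covariate report. Among
candidate adjustments (ATT IPW, stabilized weights, 1:1 nearest-neighbour
matching on the logit score with a 0.2-SD caliper, without replacement, in
random order under a fixed seed), selection prefers candidates that discard
no observations and breaks ties by fewer discards, then name; matching is
considered only when every no-discard candidate exceeds the 0.1 max-|SMD|
threshold. Weight truncation (99th percentile) exists as an option and is
off by default.

## The sensitivity battery

The default grid runs eleven dementia-model variants — basic ITT and
per-protocol; dropping observations censored during the grace period;
dropping rows whose covariate visit falls after time zero; re-running
eligibility with pre-baseline HL retained and dates reset to study entry;
and six extra-adjustment variants (social isolation + mood disorder, head
injury, HL ascertainment source, hospital-use category, primary-care
category, both healthcare categories) — plus nine negative outcome
controls. All sensitivity variants except basic per-protocol are
intention-to-treat. Extra-adjustment variants repeat the whole chain
(propensity, weights, balance selection, estimation) with the enlarged
covariate set; the primary-care variants restrict to the linked subsample
because only it carries primary-care counts. Negative-control runs
re-apply outcome-specific exclusions (prior control-outcome events) and are
reported with per-outcome intervals, uncorrected for multiplicity, matching
standard practice for bias detection rather than inference.

E-values use the ratio form E = R + sqrt(R(R−1)) with
R = max(RR_obs/RR_true, RR_true/RR_obs), evaluated against candidate true
ratios of 1.00 and 0.86.

The "combined covariate effect" regresses the outcome on z-standardized
propensity scores within arm strata and pools the per-SD log risk ratios by
inverse variance. The stratum model is a modified Poisson regression with a
robust (sandwich) standard error, so the coefficient is a log risk ratio
directly. Both the standardization and the pooling rule are this package's
documented choices — "normalized" propensity scores have no canonical
definition — and are not guaranteed to match any other implementation's.

# The synthetic cohort generator

Because the motivating cohort is access-controlled, the generator emits
synthetic data with the same *structure*: a participants table (birth
month, sex, ethnicity, education, Townsend-style deprivation, region,
primary-care-linkage flag, death date), assessment visits (SiN if
administered, the paired hearing questions, a general-cognition score G,
social isolation), an EHR event stream (HL, HA, implant, dementia,
tinnitus, mood disorder, head injury, nine negative-control classes;
primary-care source only for linked participants), and annual
healthcare-contact counts. A latent-truth sidecar retains true HL onsets,
counterfactual dementia dates and the latent healthcare-use propensity for
recovery tests; no analysis stage reads it.

## Mechanisms

* **Healthcare-use confounding and detection bias.** A latent
  healthcare-use propensity drives annual primary-care and hospital
  counts, can raise HA uptake (`conf_healthcare_on_exposure`) and the true
  dementia hazard (`conf_healthcare_on_outcome`), and — through the
  participant's observed pre-entry hospital-use category — raises the
  probability that an occurred dementia (or negative-control condition) is
  *recorded* (`detection_bias_strength`, extra log-odds per category).
  Recording is a Bernoulli thinning of occurrence: this separation is what
  lets adjustment for observed healthcare-use categories move estimates.
* **Dating error.** For participants without primary-care linkage the
  onset becomes *recordable* only after an exponential delay
  (`hl_dating_error_years` mean). Recorded dates stay anchored to actual
  visits and EHR codes, so the realized lateness is the delay rounded up to
  the next ascertainment opportunity. The cohort being emulated gives no
  quantitative prior for this magnitude; the preset default of 5 years is a
  modeling choice.
* **Treatment effect.** The effect is built as pointwise risk
  proportionality, F_treated(t) = a · F_control(t) with
  a = exp(`true_log_rr_treatment`), attached to the assigned strategy
  (initiation within `effect_grace_years` = 1 of the recorded HL date).
  This makes the marginal risk ratio in the treated equal `a` exactly over
  any follow-up window and under any independent censoring — the property
  that effect-recovery tests rely on. The cost is stylization: the effect
  follows assignment rather than accruing from the initiation date.
* **Confounder alignment.** HA uptake and the dementia hazard condition on
  the covariate values the analysis can see: age at the recorded HL date
  and the SiN/G measurements from the visit closest to it (the same visit
  the covariate-anchoring rule picks), falling back to baseline and latent
  values for participants who never enter the trial. Measured-covariate
  adjustment can therefore remove all non-healthcare confounding — by
  design, so that what remains after basic adjustment is exactly the
  healthcare-use mechanism.

## Default parameters

Structural defaults follow the emulated study: entry assessments 2006–2010,
records to the end of 2022, 45.8% primary-care linkage, repeat-assessment
attendance of 4% and 15%, and HL ascertainment shares of roughly 55/42/3%
self-report/SiN/EHR in the analytic sample. The SiN distribution among HL
cases (mean −5.9 dB, SD 2.3) matches the analytic sample's published
descriptives; with the −5.5 cutoff this reproduces both the
self-report/SiN split and the large complete-case loss from unadministered
SiN tests (about 40% of otherwise eligible rows, driven almost entirely by
the SiN covariate, as in the source study).

Two scale defaults deliberately depart from the emulated study's marginal
rates. HA uptake among ascertained HL is ~15% at baseline covariates
(published UK uptake among hearing-impaired adults is 15–30%; the source
cohort's 6.8% is unusually low) and cumulative dementia risk over follow-up
is ~10% (plausible for an HL cohort aging into its seventies). At the
simulation sizes the analysis plan fixes (thousands to tens of thousands of
participants), these rates give event counts from which calibration and
recovery are actually measurable; the source study's sparser marginals
would leave about one treated event per replicate at the smallest design
size, and no estimator property can be demonstrated on that.

The scenario library pins five presets: `null` (all effect parameters
zero), `protective` (true marginal ATT risk ratio 0.86), to a
`healthcare_confounded` preset using the moderate mechanism strengths
(0.5/0.3/0.4), `dating_error` (5-year mean lateness), and `combined`
(protective truth 0.9 masked by strengthened confounding, detection bias
0.6 and dating error), the last tuned so that the basic estimate exceeds
the healthcare-use-adjusted estimate in well over 90% of replicates — the
qualitative pattern the preset exists to produce.

## What passing tests do and do not show

The generator's covariates are exactly measurable where the study's are
noisy proxies, its EHR capture of HA is complete, missingness is driven by
test administration rather than informative refusal, and the treatment
effect is homogeneous. Calibration, balance and recovery results on this
synthetic cohort therefore validate the *pipeline* — the ascertainment
rules, the weighting, the estimators and their variances — not the absence
of bias in any real cohort. In real data the residual confounding the
sensitivity battery is designed to expose (healthcare use, dating error)
may coexist with mechanisms the generator does not model.

## Simulation sizes used by the test suite

The acceptance-level checks run at the sizes the analysis plan fixes: null
calibration with 500 replicates of 5,000 participants (CI excludes 1 in
5% ± 2%); protective-effect recovery with 100 replicates of 50,000
participants (mean estimate within 3 Monte-Carlo SEs of 0.86, also with
the propensity or the outcome model deprived of the strongest measured
confounder); the combined-preset ordering with 100 replicates of 20,000;
and balance achievement with 100 replicates of 20,000 (max |SMD| < 0.1 in
at least 95%). Unit tests use smaller cohorts chosen for speed.

# Known limitations

* The candidate adjustment menu (ATT IPW, stabilized weights, 1:1 caliper
  matching) is representative, not exhaustive; genetic, exact and
  coarsened-exact matching and machine-learned propensity models are out of
  scope.
* Death is treated as censoring, as in the emulated protocol's follow-up
  definition; competing-risks estimators are not provided.
* Missing data are handled by complete-case analysis only; multiple
  imputation is out of scope.
* The weights-fixed sandwich understates the (usually small) contribution
  of propensity estimation; the bootstrap mode exists as the cross-check.
* Time-varying treatment (beyond the single grace-period assignment) and
  sustained-use verification are not modeled; the intention-to-treat arm
  uses initiation only.
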