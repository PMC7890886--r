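---
title: "Diagnosing differential non-response over time: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing differential non-response over time: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(respdrift)
```

`respdrift` asks one question of a repeated cross-sectional survey: *is
the decline in response over time plausibly biasing the estimated time
trends in the outcomes?* This vignette documents the statistical content
of each step, the synthetic survey generator used to validate the
framework, the operational thresholds, and the design decisions taken
where the methodology is genuinely open.

## Data model and assumptions

Three tables drive everything:

* a **sampling frame** — one row per invited person per wave, with age,
  sex, ethnicity, district and a response flag, available for
  respondents and non-respondents alike (the setting created by
  registry linkage);
* an **outcome table** for respondents only — sport-participation
  frequency (times/year), TV hours/day, household income;
* **population margins** — population counts per age-group x sex x
  ethnicity x district cell per wave.

Waves are treated as independent cross-sections: nobody is followed
longitudinally and repeat invitations are not modelled. Analyses are
complete-case on the four frame demographics; income missingness only
excludes records from the income-adjusted step-4 models, since that is
the one place income enters. Ages are banded 16-24, 25-44, 45-64, 65-75;
eligibility is 15-75 and the eligible age 15 joins the lowest band
(the banding leaves it unassigned otherwise — a documented choice, not a
fact about any survey). Income is banded against two reference incomes
with intervals `[0, social minimum)`, `[social minimum, modal)`,
`[modal, 2 x modal]`, `(2 x modal, Inf)`; the closure of the upper band
honours "more than twice modal" literally and keeps the partition
exhaustive. Sport participation is dichotomised at >= 46 times/year
(weekly), TV at >= 3 h/day.

Time enters every model as `(wave_year - first_wave_year) / 2` so one
unit is one biennial interval; intercepts therefore refer to the first
wave, and "per 2 years" odds ratios are the natural trend scale.

## Step 1: who responds, and is the decline differential?

A pooled logistic regression of the response flag on the wave index and
the demographic determinants (references: age 25-44, male, western)
gives the overall trend OR per interval and the demographic response
gradients. Subgroup-differential decline is screened by adding
`time x covariate` terms and comparing nested models with a
likelihood-ratio test, flagged at `interaction_alpha = 0.10` — the
conventional, more liberal level for interaction screens; per-term Wald
statistics are attached for transparency. Stratified fits (one logistic
model per covariate level, adjusted for the remaining determinants,
matching the adjusted pooled model) report the per-level trend ORs, and
`cumulative_change(or, m) = 100 (1 - or^m)` converts a per-interval OR
into the percent change in response odds over `m` intervals.

Confidence intervals are Wald intervals on the log-odds scale with
z = 1.959964. Invitee-level records are aggregated to binomial cell
counts before fitting; for models in categorical covariates and the
wave index these are sufficient statistics, so estimates, standard
errors and likelihood-ratio statistics are identical to the
record-level fit while simulation studies run orders of magnitude
faster. Complete separation and rank-deficient designs are detected and
reported as errors naming the offending term; a single-wave frame
cannot support a time trend and says so.

## Step 2: is outcome variation collapsing?

For each continuous outcome, the per-wave sample SD (n-1 denominator)
is computed by subgroup on the raw scale (times/year, hours/day), on
respondents only; waves where the outcome was not collected are omitted
rather than zero-filled. Whether variation "changed" needs an
operational rule — visual judgement does not transfer to software — so
the package fits an ordinary linear trend of SD on the wave index and
flags when the slope is significant at `significance_alpha = 0.05`
**and** the fitted first-to-last relative change exceeds
`sd_change_threshold_pct = 25`%. Fitted endpoints are used for the
magnitude so a single noisy terminal wave cannot decide the answer; with
heavy-tailed outcomes (sport counts) per-wave SD estimates are
themselves noisy. Both raw ingredients (the full SD series and the test
table) are always reported so an analyst can apply their own judgement.

## Step 3: does weighting change the story over time?

Post-stratification weights per wave are
`w_c = (N_c / N) / (n_c / n)` over the age x sex x ethnicity x district
cells, normalised to mean 1 within a wave (prevalence estimates are
scale-invariant; normalisation just fixes the emitted weight files).
When some populated cell has no respondents, exact cell weighting is
impossible and the package rakes instead: iterative proportional
fitting over the four one-way margins, run to a 1e-10 tolerance on
margin shares (typically a handful of iterations). A margin level with
population but no respondents at all is renormalised away with a
warning. Both paths are recorded in the weight attributes. No weight
trimming is applied by default, matching common municipal practice for
cell weighting with moderate cell ratios; a cap can be imposed by
post-processing the emitted weights.

The diagnostic quantity is the per-wave difference (weighted minus
unweighted prevalence, percentage points). Its linear trend is flagged
when significant **and** the fitted change exceeds
`prevalence_change_threshold_pts = 2` points — about twice the
wave-to-wave noise of a per-wave prevalence at a few thousand
respondents, and small enough that any materially misleading
compositional drift would exceed it. Summaries report the mean and the
IQR of the differences; quartiles interpolate linearly between closest
ranks (`quantile(type = 7)`), stated because IQR values are reported to
one decimal.

Weighting repairs selection that depends on the cell variables only
(missing at random given cells). If response depends on the outcome
itself, weighted and unweighted estimates are biased alike — which is
exactly why step 3 is read jointly with steps 2 and 4 rather than as a
stand-alone correction.

## Step 4: are the associations drifting?

Per wave, each dichotomised outcome is regressed on age group, sex,
ethnicity and income band (logistic, unweighted — the weighting story
belongs to step 3; income reference level "low"). Waves where a
covariate level is empty or the fit separates are recorded as failures
and skipped, not fatal. Each term's log-OR series is then regressed on
the wave index with inverse-variance (fixed-effect meta-regression)
weights `1/se^2`, respecting the very different precision of early
high-response and late low-response waves; an unweighted variant is
available as a sensitivity analysis. The per-term flag is
`p < significance_alpha`.

## The checklist

The verdict per outcome x dimension cell is

> **Y** iff step 1 flagged differential response **and** at least one of
> steps 2-4 flagged a concurrent change.

This conjunction is the minimal rule consistent with the framework's
logic: association drift without any differential response (step 4
alone) cannot be caused by non-response and is reported as a finding
about the population, not as a bias signal. Missing step results
propagate as "not assessable", never as a silent "N". Whether a
variance change *without* differential response should flag is not
decidable from the framework's published applications; under the
conjunction rule it does not, and the rule is a documented choice.

Because a dimension aggregates several trend tests (four age levels,
three age terms, and so on), the checklist flag for steps 2-4 applies a
Bonferroni-adjusted level `significance_alpha / k` across the
dimension's k tests, together with the magnitude gates; the per-level
tables keep the unadjusted flags for inspection. For step 4 the
magnitude gate is a fitted whole-series OR change of at least
`or_change_threshold = 1.5`-fold: the standard error of a fitted
whole-series log-OR change is around 0.1 at waves of a few thousand
respondents, so a smaller gate (say 1.25-fold, i.e. 0.22 on the log
scale) sits within 2.5 sigma of a null trend and would regularly be
exceeded by chance exactly when the slope also reaches nominal
significance. At 1.5-fold (0.41), a null series essentially never
passes both gates, while a log-OR moving from `log 0.6` to `log 1.0`
(0.51) across a series — the kind of gradual association drift the
framework is meant to surface — passes comfortably.

## The synthetic survey generator

`simulation_design()` defines the generating model; `simulate_survey()`
draws from it. Outcomes are generated for *every* invitee, so the
ground truth (analytic population prevalence per wave, mixture over the
demographic cells) is known exactly, and are emitted only for
responders — mirroring the fundamental observability constraint of real
surveys. A single seed governs all randomness through per-wave
substreams; identical design and seed give byte-identical tables.

Default conditions emulate a 12-wave biennial municipal survey,
1995-2017:

* 11,400 invitations per wave (a 22-year series of ~137,000 invitees);
* a demographic mix over 4 age bands x 2 sexes x 2 ethnic groups x 2
  districts, with a larger non-western share in one district;
* response odds higher for older people (OR up to 1.54), women (1.29)
  and the western group (non-western 0.51), with the reference-cell
  intercept solved numerically at design construction so the overall
  first-wave response is 47%;
* per-interval trend ORs of 0.90 / 0.91 / 0.93 / 0.96 across the age
  bands and a 0.97 multiplier for the non-western group — differential
  decline is the default, because that is the situation the framework
  exists for. The endpoint response rate is whatever these trends
  imply (~22-24% in the final wave): when a printed endpoint and
  printed per-stratum trend coefficients conflict, the coefficients
  define the generating model;
* sport participation as an over-dispersed negative-binomial count
  (reference mean 35 times/year, size 0.23, giving SD ~ 73 — large
  spread at a mean well below the weekly cut) collected from 1999
  onward; TV hours as a gamma variable (reference mean 2.5 h/day,
  shape 1.8, SD ~ 1.9) collected through 2015; household income as a
  log-normal with subgroup shifts. Subgroup effects on the outcomes are
  deliberately moderate, sized so that the weighted-minus-unweighted
  prevalence differences have mean near 0 with an IQR of about +/- 1
  point and no strong subgroup trend — the regime of a well-behaved
  survey whose weighting corrects little, which is the right null
  against which the checklist's specificity is meaningful;
* oversampling of the non-western group at 1.5x invitation probability
  from 2005 onward. Oversampling changes only invitation probabilities,
  never an individual's response propensity or outcomes, and the
  margins table always reflects the population mix.

Outcome-dependent selection is available through `mnar_schedule()`: the
dichotomised outcome indicator enters the response log-odds with a
coefficient interpolating linearly from a first-wave to a last-wave
value, optionally restricted to one subgroup. The recorded escalating
scenario, `design_mnar_escalating()`, ramps the weekly-sport
coefficient from 0 to -2.5 within the non-western group — by the final
wave, a weekly-sporting non-western invitee has e^-2.5 ≈ 0.08 times the
response odds of a non-sporting one. A bernoulli outcome family is also
available for tests that need directly specified cell prevalences.

What the generator does **not** emulate: real-world changes in survey
administration (delivery mode, recruitment campaigns), item
non-response within returned questionnaires, household clustering,
longitudinal overlap between waves, and fine-grained geography. Passing
checks on this generator therefore demonstrate that the framework's
machinery is correct and well-calibrated under clean selection
mechanisms, not that it detects every failure mode of a real fielded
survey.

## Numerical choices

* Logistic fits: `stats::glm` on aggregated binomial counts; reported
  log-likelihoods are invitee-level Bernoulli values.
* Separation guard: a coefficient beyond 15 on the log-odds scale with
  a standard error beyond 10 is treated as separation and reported.
* Raking: tolerance 1e-10 on margin shares, cap 2000 iterations.
* SD: sample (n-1) denominator, missing below two observations.
* IQR: linear interpolation between closest ranks.
* Trend tests on 3+ points use `stats::lm` (t-test for slopes of
  observed series, z-test for the inverse-variance meta-regression of
  log-ORs, whose weights are treated as known).
* Degenerate inputs fail loudly (empty strata, single-wave trends,
  constant covariates) except per-wave association fits, which record
  failures so the surviving waves can still carry a trend.

## Validation problem sizes

The test-suite and acceptance script exercise the framework at the
sizes that make each property measurable: closed-form oracles on
hand-countable 2x2 tables and a 200-record brute-force likelihood
comparison; weighting identities on exact constructions and a
three-wave, 120,000-invitations-per-wave run (~50,000 respondents per
wave) for the large-sample bias bound; coverage, power and type-I
calibration over 50 seeded replicates at 5,000-10,000 invitations per
wave; and end-to-end specificity/sensitivity over 50 replicates each of
the default missing-at-random design and the escalating-MNAR scenario
at the full default size.

## Limitations

The framework evaluates whether the *risk of bias changed over time*;
it cannot certify that any single cross-section is unbiased, and it is
blind to selection on characteristics absent from the frame. The
checklist's thresholds are operational defaults, not discovered
constants: all of them are exposed in `analysis_config()` and the
underlying series are always emitted so that a reviewer can re-draw the
line. Weighting uses the four frame demographics only; calibration to
continuous totals and propensity-score reweighting are intentionally
out of scope.
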