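---
title: "Modelling the burden of iron-deficiency anemia and fortified infant cereals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the burden of iron-deficiency anemia and fortified infant cereals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idaburden)
```

## The problem and the model

Iron-deficiency anemia (IDA) in children aged 6–23 months impairs
development during a critical window and carries lifelong consequences:
lower cognitive attainment (hence lower adult earnings), reduced physical
capacity, and — for severe cases — excess mortality. Fortified infant
cereals (FIC) raise iron intake during weaning and with it hemoglobin (Hb),
so population-level consumption patterns shift the Hb distribution and the
burden that hangs off it.

`idaburden` implements a comparative risk assessment of that burden. The
chain is:

1. **Population stratification.** A national birth cohort is split into ten
   socioeconomic (SES) deciles, each with births, mean Hb and a share of
   household income (the packaged fixture holds the 2017 Indonesian cohort:
   3.92 million births; decile Hb means from 10.4 to 11.2 g/dL). Deciles
   1–3, 4–7 and 8–10 form wealth tertiles (configurable cuts), which is the
   resolution at which consumption is observed.
2. **Hemoglobin machinery.** Each decile's Hb is modelled as normal with the
   observed mean and a common dispersion of 1.4 g/dL (only one dispersion is
   reported at population level; it is overridable per decile). Anemia
   severity uses the WHO bands for children 6–59 months by default — severe
   below 7, moderate 7–9.9, mild 10–10.9 g/dL — applied to
   altitude-adjusted Hb (WHO decrement table, configurable). A literature
   attribution share (default 0.46, the midpoint of the reported 25–67%
   envelope) restricts anemia to IDA.
3. **Dose–response.** Consumption raises Hb with a lag: a linear ramp
   reaching a maximum of 0.87 g/dL after 6 months of one daily serving. The
   maximum is the meta-analytic effect of micronutrient-fortified milk and
   cereal products on child Hb; the ramp shape is an assumption (the source
   shows a trajectory but no functional form), so a step alternative ships
   for sensitivity analysis.
4. **Counterfactual shifting.** The population is partitioned by consumption
   duration; removing (or adding) the duration-specific effect per stratum
   yields a finite normal mixture — the hypothetical Hb distribution with no
   fortification, or under a policy scenario. All scenarios, including the
   observed one, are evaluated through the same mixture machinery, so
   identities (zero effect ⇒ zero difference) hold exactly rather than to
   approximation error.
5. **Burden accounting.** IDA prevalence per stratum becomes production
   losses (millions USD) and DALYs (thousands) through three channels
   (below).
6. **Scenarios and uncertainty.** Policy scenarios transform the
   consumption profile or the effect model and are compared pairwise against
   current consumption; a Monte Carlo probabilistic sensitivity analysis
   (PSA) re-runs the whole chain under parameter uncertainty.

## Consumption: monthly curves and duration distributions

Consumption is observed two ways, and the package keeps both:

* **Monthly share curves** — the fraction of children consuming FIC at each
  month of age 6–23, overall and per wealth tertile. The fixture anchors the
  printed values (46% at month 6, a 63% peak at month 7, 25% at 12, 13% at
  18, 9% at 23 overall; 39/49/52% at month 6 and 18/26/28% at month 12 by
  tertile) and interpolates linearly between anchors, because only anchor
  months are tabulated. The per-tertile peak at month 7 is not printed; the
  fixture scales each tertile's month-6 share by the overall peak ratio
  63/46.
* **A duration distribution** — 26% never consume; among consumers 17%
  stop before 3 months, 21% consume 3–5 months, 25% 6–11, 11% 12 or more.
  The fixture spreads each band uniformly across its months. The consumer
  median is then exactly 5 months, matching the reported median (reported
  durations-of-use medians exclude never-users; with 26% zeros a
  full-population median of 5 is arithmetically impossible under these band
  masses).

Decile-level evaluation needs a duration distribution *per tertile*, which
is not observed. We derive it from the tertile share curve by a survival
construction: the share consuming at month *m* is read as the probability of
still consuming at *m* (monotonized from the right, since the raw curve
peaks at month 7), consumption is anchored at month 6, and the normalized
decrements give the conditional duration distribution. Because churn makes
ever-consumers (74%) exceed the peak monthly share (63%), the never-consumer
mass cannot come from the same curve; tertile ever-consumer fractions are
set proportional to the tertile's peak share and normalized so their
births-weighted mean is exactly 74%. This one construction is used for
every scenario, so scenario orderings are structural rather than artifacts
of mixed constructions.

## Burden channels

With `N[d,s]` the number of IDA cases of severity `s` in decile `d`
(births × IDA prevalence):

* **Impaired physical activity (YLD, childhood):**
  `sum N[d,s] * DW[s] * exposure_years`, with `exposure_years = 1.5` (the
  6–23-month window) and anemia disability weights 0.004/0.052/0.149.
* **Cognitive impairment (YLD + earnings):** all IDA-positive children carry
  a lifelong cognitive sequel: DALYs are `N_IDA * DW_cog * L(e)` where
  `L(e)` is discounted life expectancy, and losses are
  `N_IDA * cognitive_income_loss * PV(d)` with `PV(d)` the present value of
  decile-specific lifetime earnings.
* **Mortality (YLL + earnings):** severe cases die with probability
  `mortality_risk_severe`; each death loses `L(e)` DALYs and `PV(d)`.

Present values use the human capital approach: annual wages over working
ages (default 15–65), growing at the average rate of the preceding decade
(default 4%/year) and discounted at 3%/year to age 1. Wages default to a
national mean (a monthly IDR 2.7 million at the 2020 exchange rate of
14,582 IDR/USD, about USD 2,222/year) scaled by each decile's income share
relative to an equal tenth. DALYs are discounted at the same 3% with no age
weighting; an undiscounted switch exists (`daly_discounting = FALSE`).

The full channel equations of the source model and its fitted parameter
values are not publicly tabulated, so `dw_cognitive` (0.024),
`mortality_risk_severe` (0.005) and `cognitive_income_loss` (0.025) are
documented, literature-conventional stand-ins, chosen once and exposed in
`default_parameters()`. Absolute burden levels therefore depend on this
calibration; difference *structure* (orderings, null identities, published
difference-row arithmetic) does not, and that is what the test suite pins
down.

## Scenarios

All scenarios act on the consumption profile or the effect model and are
evaluated against the same unexposed baseline (each decile's observed mean
minus the expected current effect under its tertile's duration
distribution):

| kind | lever |
|---|---|
| `CURRENT` | identity |
| `NO_FORTIFICATION` | effect zeroed (cereals unfortified) |
| `EXTEND_SHORT_PLUS2` | consumers of 1–2 months consume 2 months longer |
| `LIFT_LOWEST_TO_MIDDLE` | tertile 1 gets tertile 2's share curve |
| `LIFT_AND_EXTEND` | the lift, plus +2 months for durations under 5 |
| `TWO_SERVINGS_ALL_PLUS2` | two servings/day for all, +2 months for short consumers |

Choices worth flagging:

* **Two servings** are operationalized as dose scaling: the ramp rises twice
  as fast (full effect after 3 months) but the meta-analytic 0.87 g/dL
  remains the ceiling by default (`serving_cap = 1`, configurable up to 2).
  How the source operationalized the second serving is not stated; treating
  the meta-analytic effect as attainable ceiling is the conservative
  reading.
* **Tertile-lift comparisons report the lowest-tertile subpopulation only**
  (both sides). The published current-consumption row for that comparison is
  roughly one third of the national total, which identifies the
  subpopulation interpretation; it is the default and a flag on
  `evaluate_burden(restrict_tertile =)`.
* **Percentage differences use the current-consumption scenario as
  denominator** — the published difference row divides by the
  with-fortification value even when the counterfactual is the baseline.
* Difference rows print integers at or above 10 and one decimal below,
  the dominant published convention.

## Probabilistic sensitivity analysis

`run_psa()` re-evaluates the base case under `n_draws` (default 10,000)
independent parameter draws and summarizes each burden component by its
mean and empirical 2.5th/97.5th percentiles — percentile rather than
normal-approximation intervals, since the object of interest is the
empirical cloud of model outputs. Families follow parameter nature: beta
for probabilities and weights, gamma for the wage, uniform over
[0.25, 0.67] for the attribution share, normal (truncated at zero) for the
Hb effect and income growth. The source's exact per-parameter distribution
table is not available, so the shipped set is a documented stand-in and the
published interval is not a package claim. Draws are independent across
parameters (no correlation structure is reported); draw `k` under seed `s`
is reproducible in isolation, so the draw matrix is identical however it is
scheduled.

## Synthetic microdata

`generate_survey()` emulates child-level records (age, decile, altitude,
measured and altitude-adjusted Hb, consumption duration) with consumption
linked to Hb *only* through the effect model, so parameter-recovery
experiments are clean by construction; an optional `wealth_confounding`
switch makes consumption rise with decile to emulate the real-world
gradient. `simulate()` on a model object generates surveys whose duration
distribution is the births-weighted mixture of the tertile survival
constructions, so the expected decile means equal the observed ones; note
its consumer median can differ by a month from the band-distribution median,
since the two duration constructions are deliberately distinct.
`estimate_decile_means()` recovers decile means by a no-intercept linear
model on decile indicators with delta-method standard errors for optional
transformations.

What passing tests show — and do not. The generator draws exact normals
within decile, independent records, no survey design (weights, clusters,
panel attrition), and no confounding by default. Recovery and convergence
tests therefore validate the estimation and accounting machinery, not the
field realism of IFLS/IDHS-style data.

## Numerical choices and degenerate inputs

* Severity bands are closed on the healthy side (`hb = 11` is not anemic;
  `hb = 7` is moderate).
* Prevalence from a mixture is computed from component normal CDFs exactly;
  empirical-family prevalence is classify-and-count, exact by definition.
* `discounted_life_years()` prorates a fractional final year.
* Duration pmfs must sum to 1 within 1e-9; income shares to 100 within 0.5.
* A constant stratum yields its value with SE 0; a single-child stratum is
  flagged `reliable = FALSE` with SE `NA`.
* All-zero consumption profiles are valid and collapse every scenario to
  the unexposed distribution exactly.
* PSA truncation is by rejection; 1,000 consecutive rejections raise an
  unsatisfiable-support error rather than silently clamping.

Problem sizes used by the test suite were chosen to keep the full run in a
few minutes while leaving Monte Carlo error far from the asserted
tolerances: 200 replicate surveys of n = 5,000 for parameter recovery
(2,000 pooled coverage checks), one million simulated children for the
mixture-shift check (common random numbers, so only duration sampling error
remains), 10,000 PSA draws for the linear-image check, and 100 random
parameter configurations for the scenario-ordering property.

## Limitations

* Burden levels inherit the stand-in channel parameters; treat levels as
  calibratable outputs, not findings. Orderings and difference arithmetic
  are the tested claims.
* Hb determinants other than FIC (maternal iron status, animal-source
  foods, wealth-correlated diet quality) are not modelled; the observed
  decile means absorb them.
* Life expectancy is a constant, not a life table; "impaired physical
  activity" DALYs cover the childhood exposure window only by default.
* The linear ramp and the survival construction of tertile durations are
  assumptions; both are isolated behind configurable objects
  (`effect_model()`, `duration_pmf_from_shares()`) so alternatives slot in.
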