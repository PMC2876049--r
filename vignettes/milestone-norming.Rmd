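---
title: "Norming and validating a milestone-based developmental screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norming and validating a milestone-based developmental screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milenorm)
```

## The problem

Developmental screening instruments for young children consist of binary
milestone items ("walks well", "stacks blocks", "names objects") organised
into domains — here gross motor, fine motor, language, and social development,
34 items each. Creating such an instrument for a new population requires
(i) normative reference ranges: for every item, the ages at which 25%, 50%,
75%, and 90% of healthy children pass it; (ii) evidence that each item behaves
well (fits its age curve, is scored consistently by different observers, and
is not an artefact of sex, wealth, or nutritional status); and (iii) construct
validity: children who by definition have delayed development should fail the
assembled screen, and healthy children should pass it.

`milenorm` implements that whole workflow and couples it to a synthetic cohort
generator with known true curves, so every stage can be exercised and checked
without field data.

## Per-item age-of-attainment curves

For each item the probability of passing is modelled by logistic regression on
decimal age $t$:

$$P(\text{pass} \mid t) = \frac{1}{1 + e^{-(a + b t)}}, \qquad b > 0.$$

`fit_item_logistic()` estimates $(a, b)$ by maximum likelihood on the pass and
fail responses ("don't know" and not-administered rows are dropped).
Non-convergence and complete separation are surfaced through
`converged = FALSE`, and an item passed (or failed) by every child is an
error, never a silent estimate — such items need human review, not a curve.

Fit adequacy is screened with the Hosmer–Lemeshow statistic
(`goodness_of_fit()`): observations are grouped by deciles of fitted
probability (tied deciles merged), and
$\sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$ is referred to $\chi^2_{g-2}$.
A fit that is poor at the 5% level triggers the *triple-split spline refit*
(`refit_spline()`): the ages $t_{35}$ and $t_{65}$ at which the original
curve predicts 35% and 65% attainment cut the age axis into three regions,
and an independent logistic curve is refitted on each. There is no continuity
constraint at the cuts — the three regional curves are free, and any
discontinuity is recorded rather than smoothed away. A region with fewer than
15 pass/fail observations (configurable) or a single outcome class falls back
to the parent curve on that region, flagged.

The refitted model is re-screened once, regionwise: the Hosmer–Lemeshow
statistics and degrees of freedom of the three regions are pooled into a
single chi-square test. Pooling keeps the re-check a single 5%-level decision;
three separate 5% tests would reject a well-specified piecewise model about
14% of the time. The screen is applied once after refitting and not recursed.

Normative ranges come from inverting the fitted curve
(`invert_percentiles()`): for a single curve the age at attainment
probability $p$ is $(\mathrm{logit}(p) - a)/b$. For a spline, each region is
solved on its own interval; with several in-region solutions the earliest age
wins, and with none (possible at a discontinuity) the candidate closest to its
own region is used and flagged `extrapolated`, as is any solution outside the
observed age range. The "35th and 65th percentiles" are throughout interpreted
as ages at fitted pass probability 0.35/0.65, not sample age percentiles.

## Covariate screen

`test_covariate_effect()` adds one explanatory variable at a time to the
age model — sex (0/1), socioeconomic quintile (entered linearly, 1–5,
keeping one degree of freedom), and height- and weight-for-age Z-scores — and
Wald-tests its coefficient at 5%. One-at-a-time models are the minimal reading
of an exploratory item screen; no multiple-testing correction is applied, and
the summary table (`summarize_covariate_effects()`) should be read as
descriptive. Normative ranges are deliberately *not* adjusted for these
covariates: a screen for a population where stunting is common must be normed
on that population.

Wealth quintiles are built Filmer–Pritchett style
(`compute_wealth_quintiles()`): standardised household assets are projected
onto the first principal component of their correlation matrix, the sign is
anchored by a designated wealth-positive asset, and quintile cuts fall at the
20/40/60/80th percentiles of the score with boundary ties going to the lower
quintile.

## Scoring

`score_children()` implements a Denver-II-style categorical rule. An item is
*age-relevant* for a child when its fitted 90%-attainment age lies strictly
below the child's chronological age (a child exactly at the boundary is not
yet expected to pass; the tie goes to the child). A domain is failed with two
or more failures among age-relevant items; one failure is tolerated. The child
fails the screen when any domain is failed.

Two recording conventions are configurable in `scoring_rules()` because the
field description leaves them open:

* items never reached because of the stopping rule count as failures for the
  categorical score (they were unreached *because* the child was failing) but
  contribute zero to the continuous score — `stop_as_fail`;
* "don't know" outcomes are treated as missing, excluded from both numerator
  and denominator — `dont_know_as_fail` flips them to failures.

The overall rule also has a stricter variant (`overall_rule = "no_failures"`)
because the two published footnote definitions conflict: "one or no failures
per domain" versus "no failures in any domain". The default follows the
per-domain one-failure allowance, which is the reading consistent with the
published all-domain pass counts.

The continuous score is simply the number of items passed per domain (0–34)
and in total (0–136).

## Observer agreement

`kappa_from_table()` computes Cohen's kappa from a 2×2 pass/fail table,
$\kappa = (p_o - p_e)/(1 - p_e)$, with percent agreement $100\,p_o$ alongside.
When both observers are constant ($p_e = 1$) kappa is undefined and the item
is reported *not assessable* rather than given 0 or 1. Bands follow the
Landis–Koch scale and a three-level reporting scale (excellent $> 0.75$,
fair-to-good $0.4$–$0.75$, poor $< 0.4$); printed interval endpoints are
ambiguous, so both 0.4 and 0.75 are assigned to fair-to-good, and intervals on
the Landis–Koch scale are closed on the upper end. Agreement is computed over
administered-in-both-sessions items only.

## Consensus flagging

`flag_items()` encodes the rule-based part of an item-selection consensus:
persistent poor fit, kappa at or below 0.6 in any reliability design, a
significant sex effect (in the age-adjusted model, matching the screen),
a same-domain item with all four percentile ages equal within 0.05 y
("exactly the same" cannot hold to machine precision on refitted data),
and a 90% attainment age past 7 y or extrapolated. A `subjective` reason can
only come from an external annotations table — it is never computed. The
ranking used by `consensus_report()` (reason count, then a fixed severity
order) is advisory only; the report nominates and never deletes.

## Construct validity

`select_matched_controls()` pairs each clinical case with a random healthy
control of the same sex and the same age to one decimal place, each control
used at most once. `validation_report()` then compares matched groups per
domain and overall: McNemar's test on the paired pass/fail outcomes (without
continuity correction, with an exact binomial supplement when fewer than 25
discordant pairs), paired *t* tests on the continuous scores, and — for the
neurodisability comparison — sensitivity and specificity with 95% Wilson score
intervals (Clopper–Pearson available via `method = "exact"`). A pair enters a
domain's denominator only when both members have at least one age-relevant
scoreable item there, which is why per-domain denominators differ.

## The synthetic cohort generator

The generator defines the study conditions end to end:

* **Item bank** (`generate_item_bank()`): 34 items per domain with true median
  attainment ages spread over 0.15–5.5 y in administration order and slopes of
  1.5–4.5 logits per year (a 25%→90% attainment window of roughly 0.7–2.2 y,
  spanning steep motor milestones to gradual social ones). A per-domain
  fraction of items (0 gross motor, 14/34 fine motor, 19/34 language, 17/34
  social) gets a three-region plateaued logit — full slope outside the
  35%–65% attainment band, one third of it inside — which is what the spline
  refit is designed to capture. Covariate effects are assigned with the
  per-domain prevalences of a field-normed instrument (sex effects rare,
  nutritional-status effects on roughly half of items) and enter additively on
  the logit scale, centred so the curve parameters describe a
  population-typical child: ±0.6 logits for sex (random sign), 0.2 per
  SES quintile step, 0.45 per HAZ/WAZ unit.
* **Population** (`generate_population()`): 1,513 children recruited by quota
  over 34 equal-width age groups on (0, 6] y (the published quota table is not
  available, so equal targets are the default); HAZ mean −1.55, SD 1.15
  (≈35% below −2, the stunting prevalence of the target setting), WAZ
  mean −0.96, correlation 0.5 with HAZ; a latent wealth score drives both the
  binary asset indicators and the true SES quintile; WHZ near the reference so
  that acute malnutrition, prematurity (≤32 weeks), medical problems, and
  pre-identified neurodisability together exclude roughly 5% of recruits.
* **Administration** (`administer_assessment()`): items in order within each
  domain; stopping after 7 consecutive failures, applied *per domain* — the
  published rule is unscoped, but the domain-structured instruments it cites
  reset between scales, and the scope is configurable; "don't know" replaces
  an administered outcome with probability 0.01 and neither extends nor resets
  the failure run.
* **Reliability sessions** (`generate_reliability_sessions()`): 56, 52, and
  124 children for the inter-observer immediate, inter-observer delayed, and
  intra-observer delayed designs, the second session flipping each pass/fail
  outcome with probability 0.01, 0.04, and 0.10 respectively, which yields the
  expected decay of agreement across designs.
* **Clinical groups** (`generate_clinical_groups()`): 80 children with
  neurodisability performing at 0.35 × chronological age and 120 with marasmus
  performing 0.75 y behind, floored at zero. The shifts are generator
  conventions (no published values exist) chosen for the severity ordering
  neurodisability ≫ marasmus > none.

What the generator does *not* emulate: real item content and examiner
behaviour, report-versus-observation differences, household-survey structure
beyond an asset vector, age-dependent covariate distributions, and
item-to-item correlations beyond those induced by shared covariates. Passing
the package's tests therefore demonstrates that the statistical machinery is
correct under a faithful stochastic model of the study design — not that any
particular field instrument is valid.

## Numerical choices and edge cases

* All fits are deterministic given the data; every random stage takes an
  explicit seed, and the pipeline derives per-stage seeds from one run seed.
* Hosmer–Lemeshow groups with zero-variance expected counts are dropped and
  the degrees of freedom reduced; fewer than three usable groups makes the
  test not assessable (reported, not rejected).
* Quintile and kappa band boundaries, the age-relevance boundary, and the
  exclusion boundary (gestation ≤ 32 weeks inclusive) are all fixed,
  documented conventions rather than silent behaviour.
* Percentile solutions outside the observed age range are returned but
  flagged `extrapolated`, and extrapolated 90% ages both flag items for
  review and mark scoring output.

## Known limitations

* **Infant dilution of sensitivity.** The earliest fitted 90%-attainment ages
  sit near 0.8–1.3 y, so children younger than about 2 y have few
  age-relevant items and can pass the categorical screen regardless of
  ability; simulated neurodisability sensitivity is correspondingly lower in
  infancy and essentially complete after 2 y. This mirrors the real difficulty
  of milestone-based screening in the first year of life.
* **Stopping-rule selection.** When covariates shift ability, children who
  reach late items are positively selected, which biases fitted curves for
  hard items slightly early. The effect is inherent to basal/ceiling
  administration designs, not an artefact of the generator.
* The item-wise logistic framework deliberately stops short of continuous
  ability (IRT) modelling, developmental quotients, and ROC-based threshold
  tuning.

## Problem sizes used by the test suite

The packaged checks run the full study-sized pipeline (1,513 recruited
children, 136 items) where the quantity under test demands it — percentile
recovery pools three such replicates — and calibrate error rates with 1,000
single-item replicates at n = 500–800 and 200 plateaued items at n = 1,446.
These sizes were chosen so that every Monte Carlo bound in the suite has
comfortable margin over its sampling noise.
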