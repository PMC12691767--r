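---
title: "Methods: aligned prevalence models and monthly microsimulation of care-allowance demand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aligned prevalence models and monthly microsimulation of care-allowance demand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcasim)
```

`ltcasim` projects demand for a seven-level cash-for-care benefit for the
population 65+.  This vignette documents the model, its assumptions, the
tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## 1. The benefit rules engine

A person's assessed care need is a number of hours per month.  Dementia
adds an automatic premium of 40 h/month *before* classification — the
package takes the view that the premium can push a person over a level
boundary, since the premium is part of the assessed total.  The classifier
returns the highest level whose (exclusive) hour bound is exceeded and
whose qualitative criterion, if any, is met:

| level | bound (h/month) | qualitative criterion | EUR/month |
|------:|----------------:|-----------------------|----------:|
| 1 | > 65  | — | 200.80 |
| 2 | > 95  | — | 370.30 |
| 3 | > 120 | — | 577.00 |
| 4 | > 160 | — | 865.10 |
| 5 | > 180 | extraordinary care | 1175.20 |
| 6 | > 180 | uncoordinated day-and-night care | 1641.10 |
| 7 | > 180 | no purposeful movements | 2156.60 |

Two deliberate choices.  First, the *strict* bound (`> 65` rather than
`>= 65`): the level criteria define the schedule, and the table of
criteria uses strict bounds throughout; the bound is a configurable field
of `ltca_rules()`.  Second, when several of the (mutually compatible)
flags are present above 180 h, the *highest* qualifying level wins.
Hours above 180 with no flag fall back to level 4.

The bundled rates are a 2025 schedule.  All monetary outputs are
constant-price at whatever schedule is configured; substituting a
different vintage rescales every monetary output linearly (a tested exact
property).  Accounting is done in integer cents, which makes the
conservation identity — yearly expenditure equals the sum of individual
cumulative payouts — exact to the cent rather than approximate.

## 2. Two-step prevalence estimation

The estimation input is a survey with assessed monthly hours for
respondents 65+.  Two logistic regressions are fitted by maximum
likelihood (`glm.fit`):

* **any receipt**: $P(\text{hours} > 65)$ on the full sample, *fully
  interactive* — each of the six sex × education cells has its own age
  polynomial, i.e. design columns $\mathbb{1}[\text{cell}] \cdot a^k$
  with $a = (\text{age}-65)/10$;
* **severity**: $P(\text{hours} \ge 120 \mid \text{hours} > 65)$ on the
  above-65 h subsample, with the age polynomial interacting with sex and
  with education but no three-way term.

Age enters as a quadratic by default (`degree = 2`).  The degree is
configurable; the quadratic was chosen once because prevalence curves of
care need over age are smooth and convex on the log-odds scale, and a
saturated degree-0 fit is retained as a testing device (it reproduces
cell-wise sample means, the ML identity).  Rank deficiency and perfect
separation abort with an error naming the offending cells rather than
returning a silently unstable fit.

Group differences are summarised by *average marginal predictions*: the
education covariate is set to one group for every respondent, predictions
are averaged, and pairwise contrasts carry delta-method standard errors
from the coefficient covariance (verified against a nonparametric
bootstrap in the test suite).

## 3. Alignment to aggregate statistics

Survey-based predictions do not match administrative benefit statistics,
so the model is *aligned*: within each age × sex cell, an additive shift
$\delta$ on the log-odds scale is chosen so that the education-weighted
prevalence equals the statistics,
$$\sum_e w_e \,\mathrm{logit}^{-1}(\eta_e + \delta) = \text{target}.$$
The left side is strictly increasing in $\delta$, so the root is unique;
it is bracketed and polished by Newton steps to a residual below
$10^{-12}$ on the probability scale.  Targets of 0 and 1 return
$\mp\infty$ (interpreted as "nobody"/"everybody").  Because the shift is
common to all education groups, within-cell education odds ratios are
preserved exactly — the central invariance of the method: *relative risks
persist, aggregate outcomes are met*.

The full model is built hierarchically per age × sex cell:

1. align the any-receipt log odds to the statistics' total prevalence;
2. align the severity log odds (weighted by the recipient-composition of
   education) to the share of levels 3–7 among recipients;
3. align *each level separately* to its own prevalence, applying the
   unconditional band log odds — so all levels within a band (1–2 vs 3–7)
   share identical education odds, since the severity equation identifies
   band-level odds only;
4. if a person's level probabilities sum above 1, renormalise and count
   the event (`renormalised_cells`; zero under the default generator).

Education-weighted aggregation of the resulting model is the identity on
the input statistics (asserted at $10^{-8}$; observed error is at machine
precision).  Alignment operates on single-year-of-age cells rather than
smoothed age profiles; with administrative statistics by single year of
age no smoothing is needed, and cell-wise alignment keeps the identity
exact.

Mortality is aligned the same way: baseline monthly hazards are scaled by
a common factor per age × sex × year cell so that expected deaths over the
projected education-specific exposures equal the aggregate targets, with
the education relative risks (default low 1.3, medium 1.0, high 0.8)
untouched.

## 4. The monthly simulation engine

Discrete monthly steps approximate a continuous-time engine; since care
status is reassigned monthly anyway, the observable resolution is
identical and the contract far simpler.  Event order within a month:

1. **January entries**: the year's cohort enters at exact age 65;
2. **care imputation** on everyone alive at month start: a fresh draw of
   the allowance level from the aligned model at the person's *care age*
   (decedents of the month receive that month's payout);
3. **deaths**: Bernoulli draws from the aligned hazards;
4. ageing by one month.

Care is imputed cross-sectionally with *no longitudinal persistence* —
an individual's level draws are independent across months given the
lookup cell.  This deliberately gives up within-person trajectories in
exchange for exact cross-sectional calibration; lifetime accounting by
education remains valid because education enters both mortality and
prevalence.  Mortality does not depend on the care level.

Lookups use age in completed years (`floor`), capped at 105, the open top
age of the statistics; no interpolation between rows.  Scenario
transformations:

* **S1** replaces the education-specific model with the pooled statistics
  (prevalence by age and sex only); mortality gradients persist;
* **S2** applies the care age $65 + 0.8\,(\text{age}-65)$ to the *entire*
  level-distribution lookup (take-up and severity alike — the package
  treats "care needs grow more slowly" as a single transformation of the
  age profile), floored to integer years;
* **S3** freezes the first simulated year's hazard surface.

Randomness comes from three named substreams (mortality, care, entry)
derived deterministically from one seed, so scenarios run under the same
seed share common random numbers; a run with `care_age_factor = 1` is
byte-identical to the baseline, and between-scenario Monte-Carlo variance
on contrasts is reduced.

A deterministic **expectation engine** (`expected_projection()`)
propagates expected counts by month of age, sex and education through the
same event order with no sampling.  It generates the aggregate death
targets, supplies the exposure composition for mortality alignment, and
serves as the oracle for Monte-Carlo runs: started from the realised
stock it is the exact conditional expectation of the engine, so replicate
means must match it within Monte-Carlo error.

## 5. The synthetic-data generator

The generator produces every pipeline input from a seeded configuration.
What it emulates — and all it claims to emulate — is the *qualitative
structure* the method assumes:

* a 65+ stock with survivorship-shaped age distribution, a female share
  rising with age, and education composition graded by birth cohort;
* a care-need survey whose hours arise from the same two-logit hierarchy
  the estimator assumes (any receipt, severity, hour buckets within
  bands, qualitative flags only above 180 h, an age-graded dementia
  flag), with an age-increasing, education-graded hour distribution;
* aggregate benefit statistics obtained in *closed form* from the
  generating logits weighted by the cohort education composition, so the
  "administrative" targets are internally consistent with the survey
  process;
* mortality with Gompertz-type baseline (about 1.3% annual risk for men
  at 65, 22% at 95, women about 35% lower), proportional improvement of
  1.5% per year, and persistent education relative risks;
* entry cohorts with educational expansion (high-education share rising
  along the cohort anchors from 6% for 1919 births to 45% for 2015
  births) and mild size growth (0.2%/year).

Default generating coefficients give roughly 2% any-receipt at 65 rising
to 50–60% above age 100, a clear low-education excess (log-odds +0.55)
and a modest high-education advantage (−0.30).  These values were chosen
once as field-realistic magnitudes; they are the *study conditions* of
the test suite, not tuning knobs.  Survey weights are ignored: the
generator draws simple random samples, so there is nothing to weight.

What the generator does **not** emulate: real administrative or survey
microdata distributions, institutional care, migration at 65+, family
demographics, hour misreporting, or sampling designs.  Consequently,
passing tests show that the *method* is implemented correctly and behaves
as designed under its own assumptions — not that its numerical outputs
match any real benefit scheme.

## 6. Numerical choices and degenerate inputs

* Alignment root-finding: bracket expansion from ±40 on the log-odds
  scale, `uniroot` at $10^{-12}$ plus Newton polish; residual tolerance
  $10^{-12}$ on the probability scale.
* Band probabilities are clamped away from exactly 0/1
  (`qlogis(min(max(p, 1e-300), 1 - 1e-16))`) before level alignment;
  zero targets short-circuit to zero probabilities.
* Infinite generating coefficients (degenerate limits used in tests)
  dominate their design cells instead of producing `0 * Inf`.
* Ages above 105 pool into the 105+ row for every lookup; the expectation
  engine carries month-of-age bins to 120 years with an absorbing tail so
  that the care-age map of old ages matches the Monte-Carlo engine
  exactly.
* Monetary arithmetic in integer cents; doubling the rate table exactly
  doubles every monetary output.
* The December cross-section is the reference month for annual prevalence
  (a fixed-month convention; no month is canonical).
* Lifetime costs are undiscounted constant-price sums; cohort members
  alive at the horizon are *censored* — their share is reported, their
  accrued costs are not extrapolated.  Empty strata are missing, not
  zero.
* `simulate(..., stratified = TRUE)` draws levels from a within-cell
  balanced uniform grid instead of iid uniforms.  Marginally each draw
  follows the model; jointly the realised shares match the probabilities
  to a few counts per cell.  The alignment round-trip test uses this
  mode: with hundreds of simultaneous cell comparisons, iid noise would
  trigger spurious 3-standard-error violations at the expected
  multiple-comparison rate, whereas balanced sampling makes the check a
  sharp detector of genuine misalignment in either direction.  The
  simulation engine itself always uses iid draws.

## 7. Problem sizes used by the test suite

The suite exercises the full chain at sizes chosen to keep Monte-Carlo
bounds meaningful: surveys of 20,000 respondents (100 replications for
confidence-interval coverage of both equations), an alignment round-trip
of about 200,000 person-months over all 82 age × sex cells, Monte-Carlo
vs oracle comparison with a 10,000-person stock over 2025–2080 (six
replicates), and 50-seed scenario batteries with 600–1,200-person stocks
for the equivalence and ordering properties.  These sizes are the
package's own choices for a fast, reproducible default run; all
generators and the engine scale to larger populations linearly.

## 8. Known limitations

* Cross-sectional imputation cannot describe the within-person
  distribution of lifetime care (only stratum means are meaningful).
* Mortality is independent of the care level; schemes with strong
  care-mortality selection would need a joint model.
* The severity equation identifies education odds at the band level only;
  within-band level differentials by education are assumed equal.
* Alignment targets are taken as error-free administrative truth;
  sampling error in the targets is not propagated.
* The education composition of a cell is assumed equal across sexes at a
  given age (cohort-driven), which real populations violate mildly.
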