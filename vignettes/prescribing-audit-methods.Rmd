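---
title: "Methods: indicators, interaction ranking and cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indicators, interaction ranking and cohort comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psychaudit)
```

`psychaudit` audits psychotropic prescribing in populations aged 65 and over
from one-day point-prevalence charts. This vignette is the package's own
account of the methods: the indicator definitions and their conventions, the
interaction-ranking model, the comparison statistics, the synthetic-data
generator, and the numerical and design choices made where the definitions
leave room.

## Data model

A cohort is a set of patients (id, integer age, gender F/M) with
prescriptions (substance, ATC level-5 code, regular or as-needed). The
interchange format is long — one CSV row per prescription, patient
attributes repeated and checked for consistency — because that is how chart
extractions arrive. A patient without psychotropics is a row with an empty
drug name; such patients stay in every denominator. The age filter (≥ 65)
is applied at read time and the number of excluded patients is retained,
since exclusions are themselves an audit quantity.

The drug registry binds canonical substance names to level-5 ATC codes and
to the two PIPS flags. The default registry covers the 49 psychotropics of
the audited cohorts; it is a data frame and a two-column-flag CSV, editable
by the user. Unknown drug names are rejected by default — silently dropping
rows would bias every indicator downward — with an explicit
`skip_unknown_drugs` escape hatch that logs what it drops.

## Indicators

All three families work on the patient's set of *distinct* substances:
a substance prescribed both regularly and as-needed counts once. The
underlying audits include on-demand drugs deliberately (point prevalence of
*exposure*), but never state how a same-substance regular + PRN duplicate
was counted; deduplication at ATC level 5 is this package's choice and is
recorded in report metadata.

* **Polypharmacy** — ≥ 3 distinct substances. The indicator set is
  originally recommended for ages ≥ 75; following audit practice it is
  applied to all cohort members (≥ 65) and the convention is written into
  the report metadata.
* **PICP** — ≥ 2 distinct substances within one category (evaluated at ATC
  level 3), or ≥ 2 anticholinergic psychotropics. The anticholinergic rule
  is a drug-property rule: an anticholinergic antidepressant plus an
  anticholinergic antipsychotic qualifies. The antiepileptic-pair rule is
  tabulated (two antiepileptics often reflect epilepsy treatment, not
  inappropriate psychiatry) but excluded from the PICP flag.
* **PIPS** — any long-acting benzodiazepine (diazepam, flunitrazepam,
  nitrazepam) or anticholinergic psychotropic. Flags live in the registry,
  not in code, so the rule lists are user-editable. Clonazepam, though
  pharmacologically long-acting, is classified under N03A and is not
  PIPS-flagged, mirroring the published rule lists.

Lithium (N05AN) is categorised with the antipsychotics, following its
placement in the published drug tables.

Denominator conventions follow the audit tables they mirror: category
shares within a "k or more drugs" row use that row's patient count;
PICP/PIPS sub-rows use the family count. Percentages are rounded half-up
to one decimal — base R's round-half-to-even does not reproduce printed
tables.

## Interaction ranking

The knowledge base classifies unordered substance pairs with raw
vocabularies taken from a subscription-grade interaction database: action
(informative, monitor, adjust dose, avoid), documentation (theoretical,
case, study, extensive), severity (mild, moderate, severe), mechanism
(pharmacodynamic, pharmacokinetic). Collapsing — monitor/adjust dose →
monitor-or-adjust, study/extensive → study — yields three ordered levels
per scale. The first-ranked interaction per patient is the lexicographic
maximum of (action, documentation, severity) ordinals: an avoid-level pair
with theoretical documentation outranks a monitor-level pair backed by
studies, reflecting that recommended action matters most when giving drug
information.

Two choices the definitions leave open:

* **Ties.** When two pairs share the identical collapsed triple the pair
  first in alphabetical order of its sorted substance names is selected,
  and the tie is counted in the report metadata. This makes runs
  deterministic across platforms.
* **Mechanism** is curated knowledge-base data, never inferred from the
  description text. The source database's adjudication rule for
  pharmacokinetic entries that carry an unexplained pharmacodynamic effect
  is a matter of expert reading and is left to the knowledge-base curator
  (the shipped fixture's mechanism labels follow the published
  classification).

Matching is by substance-name pair at level 5, not by ATC class, because
interaction databases list substance pairs. The shipped fixture encodes the
15 pairs inferable from the published first-ranked interaction table; it is
a synthetic stand-in for a licensed database and is deliberately sparse —
synthetic cohorts therefore show lower interaction prevalence than the
published audits, whose database covered far more pairs.

## Comparison statistics

Proportions are compared on the 2×2 table with Pearson's chi-square without
continuity correction, switching to the two-sided Fisher exact test when
any expected cell is below 5 (strictly below: a table with expected cells
exactly 5 is still tested by chi-square). Uncorrected chi-square is the
common default at audit sample sizes, and on null tables its p differs from
Fisher's by an amount that shrinks like 1/√N — the test suite checks the
agreement at expected cells in the thousands. Continuous variables use the
Mann-Whitney U-test (exact for small untied samples, normal approximation
with tie correction otherwise). Significance is declared at p < 0.01.

The logistic procedure models having ≥ 1 matched interaction among
patients with ≥ 2 psychotropics. Predictors: gender (male = 1 — the
published coding direction is unstated, so the package fixes and documents
one), age and number of psychotropics (continuous), and the four category
flags (0/1). Step 1 fits univariate models; step 2 the fully adjusted
model; step 3 refits over predictors with Wald p < 0.25 in *either* earlier
step (the screening rule's "one of the first steps" is read as a
disjunction and flagged in the report). Odds ratios carry Wald 95%
intervals. Multicollinearity is screened by regressing each predictor on
the others: tolerance = 1 − R², VIF = 1/tolerance. Perfect separation is
detected from the fitting warnings plus an exploding Wald standard error;
affected estimates are suppressed and flagged rather than printed.
Constant predictors (e.g. a category no one uses) are dropped with a
message.

## Synthetic cohorts

The generator emulates the audited population's *marginals*, which are all
the published audits report:

* ages: normal, mean 84.6 (SD 7.2) or 84.3 (SD 8.1) for the 2000-/2016-style
  presets, rejection-sampled above 64.5 and rounded to integer years, so
  every generated patient passes the inclusion filter;
* gender: Bernoulli with male fraction 0.264 / 0.339;
* per-patient distinct-psychotropic counts: a distribution over 0..6,
  calibrated so the expected ≥ 1 / ≥ 2 / ≥ 3 shares are 59.6/24.4/6.2%
  (2000) and 80.5/56.0/29.6% (2016) and the mean counts are 0.91 and 1.84,
  matching the published thresholds, ranges (max 4 vs max 6) and per-person
  averages simultaneously;
* drugs: given a count *k*, *k* distinct substances drawn proportional to
  the published per-drug patient counts; about 30% of prescriptions are
  marked as-needed (the audits report prescriptions "regular and on
  demand" without a split; the fraction is configurable).

Proportional sampling without replacement is implemented as systematic
probability-proportional-to-size sampling in randomised order with capped
inclusion probabilities. The point of this design is that each drug's
marginal inclusion probability is *exactly computable*
(`expected_drug_prevalence()`), so prevalence-recovery tests compare
observed shares against a true configured value instead of an
approximation; successive weighted draws would have no closed-form
marginal.

What the generator does **not** emulate: joint structure. Drug choice is
independent of category given the count, so category co-occurrence,
ward-type clustering, dementia status and deliberate co-prescribing
patterns are absent. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline computes its definitions correctly at
realistic scale — not that real cohorts would show the same interaction
prevalence or regression structure. Cohort-specific regression odds ratios
are explicitly out of reach without patient-level data.

## Numerical choices and degenerate inputs

* Percentages: half-up at one decimal, via `floor(x·10 + 0.5)` with a
  10⁻⁹ guard against binary representation of halves.
* Empty cohorts: indicator tables return zero counts with `NA`
  percentages; no division by zero.
* Duplicate identical prescription rows collapse with a warning (chart
  exports commonly duplicate); inconsistent patient attributes across rows
  are an error.
* All randomness is seeded: a cohort configuration carries its seed,
  generation restores the caller's RNG state, and re-running the audit on
  identical inputs produces byte-identical report bundles.

## Problem sizes used by the test suite

The oracle-equivalence tests run brute-force first-ranked selection on
1,000 random patients and nested-loop indicator recounts on 20-patient
fixtures; exact-test oracles enumerate all margin-fixed 2×2 tables and all
rank assignments at group sizes ≤ 4. Parameter recovery plants a known
antidepressant log-odds (0.9) in a simulated population of 2,000 and
requires the step-3 estimate to land within its own Wald interval of the
truth; prevalence recovery checks 5,000-patient cohorts against the exact
configured inclusion probabilities with 99% binomial bands (allowing the
handful of boundary misses expected among 49 simultaneous bands). These
sizes keep the whole suite under half a minute while leaving the
statistical checks well-powered.

## Limitations

The indicator catalogue is the audit's own (no Beers/STOPP/NORGEP lists),
though both the registry flags and the knowledge base are plain editable
tables. Doses and administration times are carried but not analysed — no
maximum-daily-dose checking. The knowledge-base fixture is illustrative,
not clinical; any real audit should load a licensed interaction database in
the documented format. And the collapsed anxiolytic-hypnotic category can
overestimate same-category combinations, a known property of these
indicators.
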