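---
title: "Methods: SRS filtering, comparison and disproportionality signal mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SRS filtering, comparison and disproportionality signal mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsminer)
```

## The analysis problem

Spontaneous reporting systems (SRS) are passive surveillance databases:
each record is one voluntarily submitted report of a suspected adverse
drug reaction (ADR), with demographics, the suspect drug, the coded event
term and its system organ class (SOC), onset timing, severity and outcome.
Because the population at risk is unknown, an SRS supports *report-count*
analyses only — descriptive comparisons between drug classes and
disproportionality statistics over drug–event combinations (DECs) — never
incidence rates. `srsminer` implements that chain for anticancer-drug
databases where the comparison of interest is monoclonal antibodies (mAbs)
versus traditional cytotoxic/targeted agents.

## Report filtering

`apply_inclusion_filters()` retains reports with: year 2016–2020;
causality assessed as certain, probable or possible; suspect drug in ATC
class L01; non-missing age (≤ 120 years), drug name and ADR term;
non-negative onset time when recorded; and no earlier retained duplicate.
Rules are evaluated in a fixed order (year, causality, ATC, missing
information, implausible age, negative onset, duplicate) and every
excluded report is attributed to its *first* matching rule, which makes
the accounting identity `n_input = n_retained + Σ exclusions` exact and
auditable. Filtering is idempotent and never raises on content.

Two gaps in common SRS practice had to be closed by explicit choices:

* **Duplicate key.** "Duplicate record" is rarely defined operationally.
  We use strict field equality on (year, age, sex, drug name, ADR term,
  onset days), keeping the first occurrence in file order. This is
  conservative: true duplicates with discrepant fields survive, but no
  distinct report is ever discarded.
* **Missing age/sex.** Real provincial databases retain a small number of
  reports with unknown age or sex and drop them per-analysis, not from
  the dataset. `crosstab()` therefore drops unknown/missing rows from the
  individual table only; note that published tables sometimes keep the
  full class total as the percentage denominator, so a column with
  unknowns can print percentages summing slightly below 100. Within this
  package, column percentages always use the observed column total and
  sum to 100 within rounding.

## Variable codings

* **Polypharmacy**: ≥ 5 concurrent medications (`flag_polypharmacy()`).
* **Impact dichotomy**: prolonged, worsened, sequelae and death collapse
  to `"effect"`; everything else is `"no_effect"`
  (`dichotomize_impact()`). Outcomes are coded 1 = effect/serious, so
  negative logistic coefficients are protective.
* **Onset bins**: day of first administration = day 0; bins same-day,
  1–3, 4–7, 8–30, > 30 days (`bin_onset()`). The first two edges are the
  clinically anchored ones (infusion-day reactions for mAbs, 1–3-day
  reactions for cytotoxics); the remaining edges follow the usual
  week/month breaks and form a total, non-overlapping partition of the
  non-negative integers.
* **Age groups**: 0–5, 6–17, 18–34, 35–59, 60–79, ≥ 80, with boundary
  ages in the younger-labelled group.
* **Percentages**: two decimals, rounded half away from zero — the
  convention that reproduces published table cells such as 13.913 → 13.91
  and 88.348 → 88.35.

## Descriptive tests

The per-table test is the **uncorrected** Pearson chi-square
(`pearson_chi2_test()`), with the two-sided Fisher exact test
(`fisher_exact_2x2()`) substituted for 2×2 tables whenever any expected
cell count is below 5 (`choose_test()`). Two deliberate choices:

* *No continuity correction in descriptive testing.* On the reference
  severity 2×2 (174/401 vs 5285/10050) the uncorrected statistic is
  X² = 4.343, p = 0.0372 — matching the published "0.037" — whereas the
  Yates-corrected value (p ≈ 0.041) does not. The Yates correction
  appears only inside the MHRA signal statistic, where it is part of the
  criterion's definition.
* *Expected-count rule for Fisher.* Published tables flag which rows used
  which test but not the rule; "any expected cell < 5" is the standard
  textbook threshold and reproduces the test choice for all large rows.

Degenerate tables (fewer than two non-empty rows or columns, or a SOC row
with a zero cell) are reported with test `"NE"` (not evaluated) rather
than a meaningless p-value.

## Risk models

`fit_logistic()` fits the severity and impact models by maximum
likelihood (IRLS via `stats::glm`), with the categorical reference levels
fixed to non-mAb, male, age 18–34, single disease, non-polypharmacy, no
past ADR history. Wald ORs and CIs come from the inverse observed
information; a fit with any |β| > 15 is flagged non-converged
(quasi-separation) instead of silently reported. Grouped 2×2 data fitted
with case weights reproduce ln(ad/bc) exactly (to numerical tolerance),
which the tests assert as an identity.

`mh_pooled_or()` implements the Mantel–Haenszel pooled OR
Σ(aᵢdᵢ/nᵢ) / Σ(bᵢcᵢ/nᵢ) with the Robins–Breslow–Greenland variance for
ln OR. Empty strata contribute nothing; the single-stratum case equals
the crude OR exactly; the pooled estimate always lies between the extreme
stratum ORs. `stratified_mab_effect()` assembles the per-stratum 2×2
(mAb exposure × dichotomised impact) across sex, age group, disease type,
polypharmacy or ADR history, with Woolf CIs per stratum
(Haldane–Anscombe +0.5 applied, and flagged, only when exactly one cell
is zero).

## Disproportionality signal mining

`build_dec_tables()` gives each report exactly one (drug, term) pair, so
for every DEC the cells a, b, c, d partition the database. The 2×2
orientation is the conventional one — b = suspect drug with other ADRs,
c = other drugs with the suspect ADR — under which ROR = ad/bc and
PRR = [a/(a+b)]/[c/(c+d)] are simultaneously consistent. (Published
footnotes sometimes swap the b/c labels relative to the printed PRR
formula; the swap leaves the ROR invariant, and the orientation used here
is the one that makes both formulas coherent at once.)

Numerical decisions:

* **Yates clamp.** χ² uses max(0, |ad−bc| − n/2)², so balanced tables get
  exactly 0 rather than a spurious positive value; the corrected value
  never exceeds the uncorrected Pearson X².
* **MHRA denominator.** The margin-symmetric (a+b)(c+d)(a+c)(b+d), the
  form that satisfies the "Pearson with continuity correction" identity.
* **Undefined metrics.** Any zero cell makes ROR/PRR/χ² undefined (`NA`);
  an undefined metric fails its criterion, so such DECs can never signal.
* **PRR interval.** The default standard error is
  √(1/a + 1/b + 1/c + 1/d) — the form used alongside the criteria this
  package reproduces; the textbook PRR error
  √(1/a − 1/(a+b) + 1/c − 1/(c+d)) is available via `prr_se =
  "textbook"`.
* **Combination rule.** A DEC signals when ROR, PRR and MHRA criteria all
  pass (intersection): published ranked signal tables are consistent with
  this rule, and it is the conservative choice for a frequentist method
  prone to small-count false positives. `rule = "union"` is available.

`rank_signals()` emits only flagged DECs, ordered by χ² descending, with
estimates at two decimals — the usual published layout.

## The synthetic-SRS generator

`sim_config()` + `generate_reports()` produce a database from: categorical
marginals (year, sex, age group, causality, disease and medication
counts), a weighted drug catalogue, an event catalogue with baseline
reporting probabilities, per-drug-class onset-bin distributions (uniform
day within bin), logistic outcome models for severity and impact
(covariates: mAb, female, multiple diseases, polypharmacy, ADR history),
and planted DECs: for a report of a planted drug, the event's baseline
probability is multiplied by the reporting-rate ratio and the event
distribution renormalised. The defaults are the marginal structure of the
reference dataset — mAb share 3.6%, five-year ramp-up concentrated in the
final year, ~54% female, serious fraction ~34%, impact fraction ~17%,
outcome coefficients of the magnitudes published for these models — so a
default run emulates the study-scale database. `expected_dec_counts()`
gives the closed-form expectation of every DEC's cells under this model
and is the oracle against which the generator is tested.

A single seed governs the whole table; fields are drawn in a documented
fixed order, so identical config + seed is reproducible byte for byte.
Seeds for replicate runs in `operating_characteristics()` are derived
deterministically from the base seed.

What the generator does **not** emulate: reporting-propensity biases
(Weber effect, notoriety bias), drug–drug interaction reporting,
within-patient correlation across reports, term co-occurrence within a
report (one term per report by construction), and secular drift in coding
practice. Passing tests therefore show that the statistics behave
correctly under a clean generative model with known truth — not that any
particular real-world database is free of those biases.

## The reference dataset

`srs_fixture()` is a deterministic table of 15,910 reports whose marginal
counts reproduce a published provincial-SRS mAb safety comparison cell by
cell: demographics, year, disease, polypharmacy and history margins per
drug class; SOC margins per drug class and — within mAbs — jointly with
patent status; severity and impact margins; the published mAb drug
breakdown; the two published onset anchors (297 mAb same-day of 575;
4,929 non-mAb 1–3-day of 15,329 known-onset) with 6 missing onsets; and
44 missing-age / 13 missing-sex non-mAb reports matching the published
per-analysis exclusions. The unpublished onset bins were fixed so the
non-mAb within-one-week share is 85.17%, matching the published summary
statement.

Joint structure beyond these constraints is *arbitrary but fixed*: each
variable is laid out in deterministic contiguous blocks (no randomness),
so the tests can assert every cell byte-stably. Two consequences to keep
in mind: (i) analyses that depend on unconstrained joints — notably
multivariable regression coefficients and stratified ORs on the fixture —
are artifacts of the block layout, not estimates of anything published;
use the synthetic generator for those. (ii) The 44 missing-age rows are
technically excludable under the missing-information rule, mirroring an
inconsistency in published practice (the rule is stated, yet age-unknown
cases are reported); idempotence properties are therefore tested on
filter-clean synthetic data.

## Problem sizes and tolerances in the test suite

Exact identities (logistic vs crude OR, MH single-stratum, formula
oracles) are asserted at 1e-6–1e-9. Stochastic properties use sizes
chosen to keep Monte-Carlo error well inside the asserted bands: the
planted-signal study uses 100 replicate databases of 50,000 reports with
one DEC at rate ratio 10 (analytic expected a ≈ 30) and 20 monitored null
DECs with expected a ≥ 10; logistic parameter recovery uses 50 replicates
of 20,000 reports with the mean estimate within 3 Monte-Carlo standard
errors per term; null-ROR centring uses 20 replicates of 8,000 reports.

## Limitations

Signal criteria quantify reporting disproportion, not causation;
small-count DECs are volatile, which is exactly why every criterion
carries the a ≥ 3 floor. The package takes causality assessments as
recorded, requires one pre-selected ADR term per report (no rule is
imposed for choosing the "main" reaction among several), and ships a
small synthetic term→SOC map rather than the licensed MedDRA dictionary.
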