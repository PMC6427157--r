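---
title: "C-NEMS-S scoring, reliability and validity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{C-NEMS-S scoring, reliability and validity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnemss)
```

## The instrument

The Chinese Nutrition Environment Measures Survey for Stores (C-NEMS-S) is a
structured in-store audit: a rater walks a store and records, for 12 food
measures, whether a designated *healthier option* is stocked, how many
species/varieties of it are on offer, its price against the regular option,
and (for fresh produce) the share of stock in acceptable condition. The 12
measures follow the staple/dish ("fan"/"cai") structure of Chinese meals:
grains, dry beans, starchy tubers, vegetables, fruits, seafood, meat and
poultry, dietary oils, milk, bread, instant noodles, and beverages with six
sub-categories (carbonated, lactose, juice, tea, plant-protein, cider
vinegar — each scored as its own availability/price line).

Seven measures name an explicit healthier option (whole grains, lean meat,
plant-based oils, low-fat milk, whole wheat bread, non-fried instant
noodles, sugar-free beverages); the remaining five (dry beans, starchy
tubers, vegetables, fruits, seafood) are wholly healthy foods whose
availability is simply the presence of any species.

`nemss_instrument()` encodes the scoring sheet declaratively — each measure
carries an availability rule (base points plus ordered species brackets), an
optional price rule, and an optional quality rule — and the definition
round-trips through a YAML config (`write_instrument()` /
`read_instrument()`) so regional variants can be expressed as data, not
code.

### Scoring rules and their edge cases

* **Species brackets count varieties of the healthier option**, and the
  bonus applies only when the option is present; the bracket lines sit under
  each "YES ..." line on the sheet. Counts below the lowest bracket earn no
  bonus (a store with whole grains but only one variety scores the 2 base
  points).
* **Starchy tubers' top bracket** is printed as "5 species = 3 pts"; we read
  it as ≥5, open-topped like every other top bracket, so a store with six
  tuber species is not pushed back into a lower bracket.
* **Milk's second availability line** (one point when low-fat varieties
  outnumber whole-fat) is a shelf-proportion judgement, not a species count.
  The audit schema records it as a 0/1 indicator in the `species_count`
  column, scored through a `{>=1 -> 1}` bracket — the one field overload in
  the schema, chosen so the long-format CSV keeps a single fixed header.
* **Equal prices score 0 except for milk**, the only measure whose printed
  rule defines an equal-price point (+1). Price is *not assessed* (0 points)
  when the healthier option is absent or either price is missing: no
  comparison pair exists, and a missing-data zero must not masquerade as a
  judgement.
* **Quality below 25% acceptable scores 0**, implied by the bracket floor.
* **Quality is assessed for vegetables, fruits and seafood only.** The
  instrument's two printed summaries disagree on meat and poultry (the
  dimension table marks a quality cell; the scoring sheet itself says "Not
  Applicable"); we follow the scoring sheet, since it is the operational
  document raters carry.
* **Incomplete observations degrade gracefully**: a missing species count on
  a bracketed measure scores its bracket component 0 with a warning rather
  than failing the store, so field data with gaps remains scoreable; a
  missing measure, by contrast, is a hard error listing the gaps.

### Attainable ranges and the footnote discrepancy

`score_range()` derives per-subscale and total ranges by brute-force
enumeration of every admissible per-measure outcome. Admissibility couples
the dimensions within a measure — a −1 price point is only reachable
together with the base availability points that presence implies — which is
why the total floor is 0 (an all-absent store) rather than the sum of the
subscale floors. For the default instrument the enumeration gives
availability 0–42, price −12–24, quality 0–9, total 0–75.

The original sheet's footnote prints availability 0–48, price −14–26, total
−14–83. Those numbers cannot be produced from the itemized rules as printed
(the full instrument appendix may contain lines the published sheet does
not show). The package **derives** its ranges and carries the printed ones
as metadata: `score_range()` reports both and warns on the mismatch. Nothing
is silently patched, and the quality range (0–9) agrees exactly.

## Reliability statistics

Two raters audit the same stores simultaneously; reliability is computed per
measure and for the composite score.

* **ICC**: the intraclass correlation form is not dictated by the study
  design alone, so we chose the standard coefficient for two fixed-in-study
  raters scoring the same stores: two-way random effects, absolute
  agreement, single rater — ICC(A,1). Absolute agreement penalizes a rater
  who is systematically generous, which consistency-type coefficients would
  forgive. It is computed from the mean-squares decomposition directly
  (`icc_agreement()`), and tests cross-check it against an independent
  `aov()`-based variance-components oracle to 1e-10.
* **Composite row**: the composite ICC defaults to the *availability
  subtotal* (the availability composite score); `reliability_report(...,
  composite = "total")` switches to the total score.
* **Kappa** is computed on yes/no availability flags with marginal-product
  expected agreement. When observed agreement is perfect, kappa is reported
  as 1 even if a marginal is degenerate (all stores stocking grains should
  read as perfect agreement, not 0/0).
* **Degenerate tables**: with zero variance across stores and raters the
  ICC is undefined and reported as `NA` — never a silent zero — with
  percent agreement always present as the descriptive fallback. This
  mirrors what happens to price and quality scores in real audits, where
  between-store variance can be too low for ICC to exist.
* **Bands**: ICC <0.4 poor, 0.4–0.75 moderate, >0.75 good; kappa <0.4 poor,
  0.4–0.6 middle, 0.6–0.8 good, >0.8 excellent. Values exactly on a
  boundary fall into the lower band.

## Known-groups validity

Construct validity is shown by the instrument separating groups with an
expected difference.

* **Total score by store type**: pooled-variance Student's t (two-sided).
  Degenerate zero-variance groups return p = 1 when means agree.
* **Availability by store type**: the study names only "a nonparametric
  test". We chose the two-sided **Fisher exact test** (full hypergeometric
  enumeration, summing all tables with point probability ≤ the observed
  table's): with 10 stores per type the cells are far too small for a
  chi-square, and this choice exactly reproduces the published p = 0.023
  for the 80% vs 20% low-fat milk contrast. Some other published
  availability p-values (e.g. 0.007 for 90% vs 30% whole wheat bread, which
  Fisher puts at 0.020) are not reproduced by this — or, as far as we can
  tell, by any single standard — test; the discrepancy is documented here
  rather than chased per row.
* **Healthier vs regular prices**: both prices come from the same store, so
  the comparison is paired: the **Wilcoxon signed-rank test**, exact by
  enumeration of all sign assignments for ≤15 informative pairs (zero
  differences dropped, mid-ranks for ties, two-sided p as twice the smaller
  tail capped at 1), and the tie-corrected, continuity-corrected normal
  approximation above that. Means and SDs are over stores where both prices
  were recorded (sample SD, n−1), averaging over stores rather than over
  products within stores. The **price premium** is
  100·(M_healthier − M_regular)/M_regular, reported to the nearest integer
  percent.
* p-values are printed three-decimal with `"<0.001"` below threshold; raw
  values are retained in a machine-readable column. No multiple-testing
  correction is applied, matching the analysis style this instrument's
  validation used.

## The synthetic-audit generator

`generate_audits(default_sim_config(), seed)` emulates the validation
study's measurement design: 10 large supermarkets (>6000 m² floor area) and
10 convenience stores, each audited by two raters simultaneously.

Calibration of the defaults:

* **Availability probabilities** per measure and store type are the
  published rater-1 store-type percentages divided by 100 (e.g. whole
  grains 1.0 in supermarkets vs 0.1 in convenience stores; lean meat 1.0
  vs 0.0).
* **Prices** are truncated normals (floor 0.01 RMB) with the published
  rater-1 means/SDs for grains, meat and poultry, milk, bread and instant
  noodles, in their stated units (RMB/0.5 kg, RMB/250 mL, RMB/loaf,
  RMB/packet). A zero SD (regular meat) is a degenerate point mass. The
  published price table has no rows for dietary oils or the beverage
  sub-categories; for these we fixed plausible retail values once
  (oils 11.0 ± 2.0 vs 9.0 ± 1.5 RMB/0.5 kg; beverages 4.0 ± 0.8 vs
  3.5 ± 0.7 RMB/250 mL) with a modest healthier-option premium, in line
  with the premiums observed on the published measures.
* **Beverage sub-items** draw independent flags with
  q = 1 − (1 − p)^(1/6), so the collapsed any-subitem flag recovers the
  published measure-level probability p.
* **Species counts** are uniform over bracket-spanning ranges (upper bound
  two above the top bracket threshold, e.g. 1–12 for vegetables), drawn
  conditional on availability; unavailable measures record 0. Milk's
  low-fat-majority indicator is Bernoulli(0.5).
* **Quality** is uniform 60–100% acceptable in supermarkets and 20–90% in
  convenience stores: supermarkets keep fresh stock in visibly better
  condition, but both ranges overlap realistically.
* **Rater disagreement**: rater 2's availability flags equal rater 1's
  except for independent flips with probability ε (default 0.05, yielding
  kappas in the published 0.5–1.0 range at n = 20 stores); species, prices
  and quality are shared between raters, with optional rater-2 price noise
  (`price_noise_sd`, default 0). Flips are independent across measures and
  stores — the simplest model consistent with per-measure kappa reporting.

What the generator deliberately does **not** emulate: store geography and
spatial clustering, seasonal availability dynamics, correlated availability
across measures within a store (a generally well-stocked store), rater
biases that persist across stores (flips are exchangeable), and price
correlation between healthier and regular options. Passing tests therefore
show that the pipeline's statistics behave correctly under the study's
marginal structure, not that the instrument is valid for any particular real
store population.

## Numerical choices

* Fisher's enumeration treats floating-point ties with the conventional
  relative tolerance (tables with probability ≤ p_obs·(1 + 1e-7) count as
  "as extreme").
* The exact signed-rank p uses twice-the-smaller-tail, capped at 1; with no
  informative (nonzero) differences it returns p = 1.
* ICC returns `NA` (undefined) for an all-constant table, and the kappa
  perfect-agreement rule precedes the degenerate-marginal check.
* Scoring is integer arithmetic throughout; subtotals are exact sums.

## Problem sizes used by the test suite

The suite checks the Fisher implementation against a binomial-coefficient
enumeration oracle for **all** 46,376 2×2 tables with N ≤ 30; kappa
monotonicity in ε over {0, 0.1, 0.3} with 200 replicates of the 20-store
design each; parameter recovery at 2000 stores per type (tolerance ±0.02);
the known-groups direction over 500 seeded replicates of the default
design; and the enumerated score bounds against 10,000 randomly generated
audits. These sizes keep every check comfortably reproducible on a single
CPU while leaving the Monte Carlo margins far from their thresholds.

## Known limitations

* The instrument definition follows the published scoring sheet; the full
  appendix form (Chinese-language) is not encoded, which is the likely
  source of the footnote range discrepancy described above.
* The snacks measure was dropped from the final instrument by its authors
  and is not modelled.
* Reliability supports exactly two raters (the measurement design); Fleiss
  kappa and multi-rater ICC generalizations are out of scope, as are ICC
  confidence intervals.
* The validity tables re-compute the published analysis *structure*; the
  study's raw store data are not deposited, so its exact reliability and
  validity values (e.g. composite ICC 0.98, totals 31.80 vs 1.90) are
  reproduced in distribution by the calibrated generator, not numerically.
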