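# cnemss

Scoring, inter-rater reliability and known-groups validity analysis for the
**Chinese Nutrition Environment Measures Survey for Stores (C-NEMS-S)** — an
observational audit instrument that rates the in-store food environment of a
retail outlet on the availability, price and quality of healthier food
options.

## Who this is for

Field teams and researchers auditing retail food environments in China (or
adapting a NEMS-style instrument elsewhere) who need a tested, reproducible
pipeline from raw audit records to instrument scores, reliability tables and
construct-validity comparisons — without hand-scoring spreadsheets.

## The instrument and its statistics

The C-NEMS-S covers 12 food measures reflecting the fan/cai structure of the
Chinese diet: grains, dry beans, starchy tubers, vegetables, fruits, seafood,
meat and poultry, dietary oils, milk, bread, instant noodles and beverages
(six sub-categories). Each audit is scored per measure on up to three
dimensions:

- **Availability** — base points when the designated healthier option (whole
  grains, lean meat, plant-based oils, low-fat milk, whole wheat bread,
  non-fried instant noodles, sugar-free beverages) is present, plus
  species-count bracket bonuses for variety; the five wholly "healthy food"
  measures are scored on species counts alone.
- **Price** — the healthier option vs the regular option: +2 if cheaper, −1
  if dearer (milk alone awards +1 for equal prices); not assessed when the
  healthier option is absent.
- **Quality** — percent of fresh stock in acceptable condition, for
  vegetables, fruits and seafood: 25–49% → 1, 50–74% → 2, ≥75% → 3.

Subtotals sum per-dimension points; the total is their sum. `score_range()`
derives the attainable ranges by brute-force enumeration of every admissible
per-measure outcome (availability 0–42, price −12–24, quality 0–9, total
0–75 for the default instrument) and warns where they differ from the ranges
printed on the original scoring sheet's footnote.

Inter-rater reliability of paired audits uses the two-way random-effects,
absolute-agreement, single-rater intraclass correlation on availability
scores,

ICC(A,1) = (MS_R − MS_E) / (MS_R + (k−1)·MS_E + k·(MS_C − MS_E)/n),

and Cohen's kappa, κ = (p_o − p_e)/(1 − p_e), on yes/no availability flags,
with the conventional bands (ICC: <0.4 poor, 0.4–0.75 moderate, >0.75 good;
kappa: <0.4 poor, 0.4–0.6 middle, 0.6–0.8 good, >0.8 excellent).
Known-groups validity compares large supermarkets (>6000 m²) with
convenience stores via a pooled-variance t test on total scores and
two-sided Fisher exact tests on per-measure availability, and healthier vs
regular prices within stores via the exact paired Wilcoxon signed-rank test,
with the percent price premium 100·(M_healthier − M_regular)/M_regular.

A seeded generator (`generate_audits()`) simulates paired-rater audit sets
calibrated to the validation study's design (10 large supermarkets + 10
convenience stores, 2 raters, published store-type availability
probabilities and price means/SDs, tunable rater-disagreement rate), so the
whole pipeline is testable with no field data.

## Worked example

```r
library(cnemss)

inst   <- nemss_instrument()
audits <- generate_audits(default_sim_config(), seed = 1)
head(score_stores(audits, inst), 4)
#> # A tibble: 4 × 7
#>   store_id store_type  rater_id availability_subtotal price_subtotal
#> 1 C001     convenience R1                           0              0
#> 2 C001     convenience R2                           1              0
#> 3 C002     convenience R1                           2              2
#> 4 C002     convenience R2                           2              2
#> # ℹ 2 more variables: quality_subtotal <int>, total <int>

total_score_comparison(audits, inst)[, c("rater_id", "mean_supermarket",
                                         "mean_convenience", "p_formatted")]
#>   rater_id mean_supermarket mean_convenience p_formatted
#> 1       R1             29.8              3.3      <0.001
#> 2       R2             28.1              5.3      <0.001

reliability_report(audits, inst)
#>    measure_id        icc icc_band  kappa kappa_band pct_agreement
#>  1 grains          1     good      1     excellent            100
#>  2 dry_beans       0.836 good      0.8   good                  90
#>  ...
#> 13 composite       0.972 good     NA     <NA>                  NA
```

Supermarkets score around 30 points against 3–5 for convenience stores
(p < 0.001 for both raters): the simulated audits reproduce the known-groups
separation the instrument was designed to detect. The composite
availability-score ICC of 0.97 and per-measure kappas between 0.6 and 1
reflect the default 5% rater-disagreement rate.

A command-line interface wrapping the same functions is installed at
`system.file("scripts", "cnemss.R", package = "cnemss")`:

```sh
Rscript cnemss.R simulate --seed 7 --out audits.csv
Rscript cnemss.R score --audits audits.csv --out scores.csv
Rscript cnemss.R reliability --audits audits.csv --out reliability.csv
Rscript cnemss.R report --audits audits.csv --out-dir report/
```

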