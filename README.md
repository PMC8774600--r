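# bpprisk

Probabilistic cumulative dietary risk assessment for benzophenone-type
photoinitiators migrating from food packaging.

## The problem

Benzophenone (BP) and its derivatives — 2-hydroxybenzophenone (2-OHBP),
4-hydroxybenzophenone (4-OHBP), 4-methylbenzophenone (4-MBP),
methyl-2-benzoylbenzoate (M2BB) and 4-phenylbenzophenone (PBZ) — are
photoinitiators in ultraviolet-cured printing inks.  They are not fully
bound in the printed layer and can migrate from packaging into breakfast
cereals, packaged juices and milk.  Risk assessors need to turn market
survey occurrence data (with many non-detects), food consumption tables
and toxicological reference points into a defensible statement about
whether the resulting dietary exposure is of concern, per age group and
for the mixture as a whole.

`bpprisk` implements that pipeline for R users: exposure simulation,
censored-data handling, margin-of-exposure and cumulative mixture risk
characterization, structure-based screening for data-poor compounds, and
sensitivity analysis — plus a synthetic market-survey generator so the
whole pipeline is testable and reproducible without access to survey
microdata.

## The model

The exposure metric is the average daily dose of analyte *j* for a
simulated person in an age group,

```
ADD = sum over food categories c of  C_c · IR_c · AF / BW · 1e-6   [mg/kg bw/day]
```

with `C_c` the concentration in category *c* (ng/g), `IR_c` the intake
rate (g/day), `AF` the absorbed fraction (conservatively 1), `BW` the
body weight (kg), and `1e-6` converting ng to mg.  Concentrations below
the limit of detection/quantification are bounded by substitution: 0 at
the lower bound (LB), the LOD/LOQ value at the upper bound (UB).  A Monte
Carlo simulation (default 10,000 iterations) draws one body weight per
person (normal) and per-category concentrations and intake rates
(lognormal bodies; the concentration family is selected normal-vs-
lognormal by a Kolmogorov–Smirnov heuristic), and reports the P50 and
P97.5 of the dose distribution.

Risk is characterized four ways:

* **MOE** — margin of exposure `POD / ADD` per analyte against its point
  of departure (BMDL10 for BP and 4-MBP, NOAEL for M2BB, PBZ and 4-OHBP),
  compared with a target MOE (100, or 200 for 4-MBP).
* **MOE_T** — cumulative margin for the common kidney endpoint
  (`BP + 4-MBP + M2BB`): the reciprocal of the sum of reciprocal MOEs,
  compared with a target of 200.
* **TTC** — 2-OHBP, which lacks animal data, is screened against the
  Cramer class III threshold of toxicological concern:
  90 µg/person/day ÷ 60 kg = **0.0015 mg/kg bw/day**.
* **RISK21** — each analyte's exposure band (P50–P97.5) is juxtaposed
  with its toxicity band (POD range) and classified low / moderate /
  high concern.

Two exposure scenarios are built in: scenario 1 assumes every food
category is contaminated at the regulatory specific migration limit
(SML; BP 0.6, 4-MBP 0.05, M2BB 0.05, PBZ 0.01 mg/kg), and scenario 2
uses measured (here: synthetically generated) occurrence data at both
censoring bounds.

## Worked example

```r
library(bpprisk)

cfg <- default_survey_config()           # 8 food categories, 7 age groups
res <- run_assessment(cfg, scenario = 2, seed = 1, n_iter = 10000)
res
#> <bpp_assessment> scenario 2 | seed 1 | n_iter 10000
#>   exposure rows: 77 | MOE rows: 140 | MOE_T rows: 28 | TTC rows: 7
#>   MOE verdicts: acceptable=140

dplyr::filter(res$exposure, analyte == "BP")
#> # A tibble: 7 x 8
#>   analyte age_group scenario bound   p50_mg_kg_day p97_5_mg_kg_day n_iter   seed
#> 1 BP      0-3              2 not_ap…     0.000121         0.000397  10000 2.30e6
#> 2 BP      3-6              2 not_ap…     0.000104         0.000418  10000 2.41e6
#> 3 BP      6-12             2 not_ap…     0.0000782        0.000366  10000 2.51e6
#> ...
```

Benzophenone is detected in every sample, so it needs no LB/UB split
(`bound = not_applicable`); its toddler P97.5 dose of ~4e-4 mg/kg bw/day
gives an MOE of ~7,800 against the BMDL10 of 3.1 mg/kg bw/day — far above
the target of 100.  The cumulative kidney-endpoint margin stays far above
its target in every age group:

```r
dplyr::filter(res$moet, percentile == "P97.5", bound == "UB")
#> # A tibble: 7 x 8
#>   age_group scenario bound percentile members         moet target verdict
#> 1 0-3              2 UB    P97.5      4-MBP+BP+M2BB  4184.    200 acceptable
#> 2 3-6              2 UB    P97.5      4-MBP+BP+M2BB  4949.    200 acceptable
#> ...
```

2-OHBP stays below its TTC threshold in all seven age groups, and the
sensitivity table attributes the adult dose variance to its drivers
(body weight correlating negatively, as it divides the dose):

```r
head(dplyr::filter(res$sensitivity, analyte == "BP"), 3)
#> # A tibble: 3 x 5
#>   analyte age_group input                  rank_correlation contribution_pct
#> 1 BP      19-65     C:cereal_3                        0.537            39.4
#> 2 BP      19-65     BW                               -0.348            16.5
#> 3 BP      19-65     IR:juice_reconstituted            0.273            10.1
```

`write_assessment(res, "out/")` serializes all tables as CSV plus a
run-metadata JSON; `inst/scripts/bpprisk-cli.R` wraps the same calls for
shell use.

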