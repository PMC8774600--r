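---
title: "Methods: probabilistic dietary risk assessment of benzophenone-type photoinitiators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic dietary risk assessment of benzophenone-type photoinitiators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `bpprisk`, the
assumptions it makes, the tunable parameters and their defaults, what the
synthetic survey generator does and does not emulate, and the numerical
choices a maintainer should know about.

## The exposure model

The package estimates the average daily dose (ADD) of each
benzophenone-type photoinitiator for a randomly simulated member of an
age group:

$$\mathrm{ADD} = \frac{\sum_c C_c \cdot IR_c \cdot AF}{BW}\times 10^{-6}
\quad \text{[mg/kg bw/day]}$$

where $C_c$ is the analyte concentration in food category $c$ (ng/g),
$IR_c$ the per-capita intake rate of that category (g/day), $AF$ the
absorbed fraction and $BW$ body weight (kg).  Assumptions:

* **One person per iteration.** A single body-weight draw is shared
  across all categories within an iteration; concentrations and intake
  rates are drawn independently across categories.  No correlation
  between category intakes is modelled, and no within/between-person
  (usual intake) decomposition is attempted.
* **Complete absorption.** $AF = 1$ by default (conservative); it can be
  set in the scenario constructors to any value in $(0, 1]$.
* **Densities.** Liquid matrices are taken at 1 g/mL, so ng/mL and ng/g
  are interchangeable; no density correction is applied.
* **Units.** Concentrations enter in ng/g; regulatory migration limits
  given in mg/kg are converted by a factor of 1000 so the $10^{-6}$
  factor yields mg/kg bw/day.

Body weights are normal (nonpositive draws rejected and redrawn — a
negligible probability for realistic anthropometry, enforced for
physical positivity).  Intake rates are lognormal.  These family choices
are fixed by convention because consumption-survey microdata are not
distributed with the package.

## Censored concentrations and distribution choice

Occurrence data are left-censored: each record is `detected`, `lt_lod`
or `lt_loq`.  Substitution bounds the truth from both sides: the lower
bound (LB) replaces censored values with 0, the upper bound (UB) with
the LOD or LOQ value; detected values are identical under both bounds.
Consequently every LB statistic is dominated by its UB counterpart, and
an analyte detected in 100% of samples needs no bound at all (the
package labels such results `not_applicable`).  Maximum-likelihood
censored (Tobit-style) estimation is deliberately out of scope:
substitution is the convention in this class of exposure assessment.

For the Monte Carlo, concentrations can be drawn two ways
(`conc_source`):

* `"fitted"` (default): a *detection mixture*.  With probability equal
  to the detected fraction, the draw comes from a parametric family
  fitted to the detected values; otherwise it resamples the substituted
  censored values (0 under LB, LOD/LOQ under UB).  Fitting the family to
  the detected body only — rather than to the substituted sample — keeps
  the fit meaningful under heavy censoring, where a single two-parameter
  family cannot represent a zero-inflated sample.
* `"empirical"`: plain resampling of the bounded values.

The parametric family is selected by fitting normal and lognormal by
maximum likelihood (`fitdistrplus`) and keeping the one with the larger
Kolmogorov–Smirnov p-value against its own fit.  This KS comparison is a
*selection heuristic*, exactly as used in practice for choosing a
distribution shape: parameters are estimated from the same sample and no
Lilliefors correction is applied, so the p-values must not be read as
goodness-of-fit tests.  Ties break toward the lognormal, the standard
family for concentration data.  Two practical notes:

* When the coefficient of variation is small, a lognormal is nearly
  indistinguishable from a normal (its skewness vanishes as
  $\sigma_{\log} \to 0$), and the KS heuristic cannot reliably separate
  them; the selection tests therefore use clearly distinguishable
  shapes.  This ambiguity is harmless downstream — in the ambiguous
  regime the two families imply nearly identical doses.
* Samples with nonpositive values skip the lognormal candidate (with a
  classed warning); samples with fewer than 8 detected values fall back
  to empirical resampling.

### Monotonicity by common random numbers

A single random substream is used per (analyte, age group), shared by
the LB and UB runs.  Because the substituted censored values satisfy
$LB \le UB$ record-by-record and all other draws are identical, every
simulated LB dose is elementwise below its UB counterpart, so P50 and
P97.5 inherit the ordering exactly rather than only in expectation.

## Exposure scenarios

* **Scenario 1 — regulatory ceiling.** Every category is assumed
  contaminated at the analyte's specific migration limit (BP 0.6,
  4-MBP 0.05, M2BB 0.05, PBZ 0.01 mg/kg).  2-OHBP and 4-OHBP have no
  SML and are excluded.  Only intake rates and body weight vary.
* **Scenario 2 — measured occurrence.** Concentrations come from the
  occurrence table at both bounds as described above.

## Hazard registry and risk metrics

The registry (`inst/extdata/hazard_registry.yaml`) encodes one or more
hazard profiles per analyte: BP carries the EFSA TDI of 0.03 mg/kg
bw/day (kept as metadata, not used for MOE), a noncarcinogenic BMDL10 of
3.1 mg/kg bw/day (the conservative end of the reported 3.1–7.4 band) and
a threshold-carcinogen BMDL10 of 18.5 mg/kg bw/day; 4-MBP reads across
from BP's BMDL10 with a target MOE of 200 (two extra uncertainty
factors); M2BB, PBZ and 4-OHBP carry NOAELs of 31.25, 300 and 100 mg/kg
bw/day with a target MOE of 100.  The EFSA group TDI of 0.01 mg/kg bw
for BP + 4-OHBP is stored as metadata only, since EFSA itself cautioned
against the grouping.  No linear low-dose extrapolation is performed for
the carcinogenic endpoint: BP is treated as a threshold carcinogen and
characterized by MOE against its BMDL10.

The margin of exposure is $\mathrm{MOE} = \mathrm{POD}/\mathrm{ADD}$
(infinite, flagged, at zero dose).  The cumulative margin for the common
kidney endpoint combines BP, 4-MBP and M2BB harmonically,

$$\mathrm{MOE}_T = \Big(\sum_j 1/\mathrm{MOE}_j\Big)^{-1},$$

and is compared against 200 — the most stringent member target, a
conservative dominance rule.  The membership is the common-endpoint set;
the P50 and P97.5 of each bound are all reported because the source
analyses do not fix a single percentile for the combined metric.

2-OHBP, lacking animal data, is screened by the threshold of
toxicological concern.  Cramer class III (assigned externally; the
decision tree itself is out of scope) gives 90 µg/person/day, which at
the default 60 kg adult converts to 1.5 µg/kg bw/day = 0.0015 mg/kg
bw/day.  The screen is a strict comparison (`dose < threshold`), applied
to the UB P97.5 dose — the conservative side.  The body weight is
configurable per run; the 60 kg default is retained even for children's
rows so that the screen matches the fixed published threshold, which is
itself defined for a 60 kg adult.

RISK21-style classification juxtaposes the exposure band (P50–P97.5)
with the analyte's POD band: *low* concern when the upper exposure times
the target MOE stays at or below the lower POD (protective at the
margin, with equality counting as protective), *high* when even the
median exposure reaches the POD band, *moderate* otherwise.

## Sensitivity analysis

Contribution to variance is the normalized squared Spearman rank
correlation: input $i$ with rank correlation $r_i$ against the dose gets
$100\,r_i^2/\sum_j r_j^2$ percent.  This is the convention of
spreadsheet Monte Carlo tools, chosen because the risk-assessment
practice this package serves reports exactly such percentages; Sobol
indices or standardized regression coefficients would be reasonable
alternatives but are not needed for comparability.  Correlations below
0.01 in absolute value are reported as 0% rather than as noise; constant
inputs (e.g., point-mass concentrations in scenario 1) are dropped
before attribution.  The sign of $r$ is kept as metadata — body weight,
which divides the dose, is expected negative.

## The synthetic survey generator

The generator replaces the market-survey microdata the analysis was
designed for.  Its default configuration
(`default_survey_config()`) emulates:

* eight food categories — three breakfast-cereal classes (59, 61, 60
  samples), three juice classes (14, 63, 59) and full-/low-fat milk
  (37, 9); 362 samples in total;
* per-(category, analyte) detection rates and lognormal concentration
  bodies moment-matched to the packaged summary table
  (`inst/extdata/survey_summary.csv`) via
  $\sigma_{\log}^2 = \log(1 + \mathrm{CV}^2)$ from the published
  arithmetic mean and SD of detected values.  The published
  geometric-mean column is *not* used: several of its cells are
  internally inconsistent with their own row (e.g., a GM above the row
  maximum), so it is transcribed verbatim for reference but never used
  as a parameter or an oracle;
* censoring: detected values are drawn left-truncated at the LOQ so
  data are internally consistent with their flags; censored records
  split 50/50 between `lt_lod` and `lt_loq` (both are substituted
  identically at each bound, so the split only affects labels); where a
  row does not state its quantification limit, matrix-level defaults
  are used (0.01 ng/g cereal, 0.11 juice, 0.21 milk, LOD = 0.3 × LOQ);
* seven age groups (0–3 … >65) with synthetic body weights and intake
  rates.  2-OHBP occurrence (absent from the summary table) is
  represented by synthetic low-level specs in the liquid categories.

Body-weight and intake parameters are **synthetic placeholders, not
survey values** — the consumption appendix underlying the original
analysis is not available.  Magnitudes were fixed once on two grounds:
plausibility for an East-Asian population (toddlers ~12.6 kg through
adults ~64 kg), and consistency with the published regulatory-ceiling
scenario, whose toddler P97.5 dose at the benzophenone SML is on the
order of $10^{-2}$ mg/kg bw/day — which pins the realistic scale of
intake-to-body-weight ratios.  Staple milk intake gets a lower
geometric SD (1.7) than episodic juice consumption (2.2), with cereals
between (2.0).  Passing tests on these synthetic data therefore
demonstrate the correctness and stability of the *pipeline* (bounding,
simulation, combination rules, screening) and qualitative agreement of
verdicts — not a reproduction of population-specific dose estimates,
which would require the real consumption tables.

Problem sizes used in the shipped checks: 10,000 iterations for
headline runs and parameter recovery, 100,000 for the closed-form
quantile comparison, 3,000-iteration runs in the end-to-end suite, and
100 replicates of n = 1,000 for family selection.

## Numerical choices

* **Quantiles**: linear interpolation between order statistics
  (R's type 7), fixed and documented since no quantile rule is imposed
  by the source conventions.
* **Seeds**: one user-facing integer seed is expanded into deterministic
  substreams (a large-prime stride modulo $2^{31}-19$), one per
  simulation, so adding a stage never perturbs earlier draws and reruns
  are byte-identical.
* **Degenerate inputs**: zero-variance distribution specs are legal and
  draw constants (enabling exact closed-form checks); constant samples
  cannot be fitted and raise a classed error; zero exposure yields an
  infinite MOE with an `acceptable` verdict rather than an error.
* **Negative fitted-normal concentration draws** are truncated at zero.
* **Serialization**: dose columns are written in scientific notation
  with four significant digits; full precision is available as JSON.

## Known limitations

* Substitution bounding, not censored maximum likelihood; bounds can be
  wide when detection rates are low.
* No intake correlations across categories and no usual-intake model —
  the P97.5 of a single simulated day overstates long-run upper-tail
  exposure.
* The TTC screen and MOE targets are only as good as the registry
  entries; the registry is data, and deliberately easy to edit.
* Verdicts on synthetic data validate machinery and orders of
  magnitude, not population-specific estimates.
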