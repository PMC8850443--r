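---
title: "Harmonizing projected crop-yield climate impacts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing projected crop-yield climate impacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropclim)
```

This vignette documents the statistical model behind `cropclim`, the tunable
parameters that matter, the numerical conventions that were fixed for
reproducibility, and the places where the design was genuinely open and a
choice had to be made. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## The harmonization problem

A corpus of crop-simulation results (maize, rice, soybean, wheat; site,
regional and country-aggregated gridded studies) reports future yields
against study-specific baseline periods ranging from the 1960s to the
2000s, under emission scenarios from several generations of climate
ensembles (SRES/CMIP3, RCP/CMIP5), with and without adaptation measures,
and with patchy climate metadata: roughly half of the simulations in a
corpus of this kind do not report the local temperature rise that drove
them. Three computations make such a corpus comparable:

1. a common **effect size** — the relative yield impact;
2. a common **time reference** — linear rescaling to the 2001–2010 baseline
   (midpoint 2005);
3. **completion of covariates** — model-based imputation of missing local
   warming, global warming and precipitation change.

## Effect sizes

The relative yield impact is `YI = (Yf/Yb − 1) × 100` (percent), defined
for `Yb > 0`, `Yf ≥ 0`, hence bounded below by −100 (total crop failure).
Relative impacts are unitless and immune to the yield-definition
differences (graded/husked/milled, moisture conventions) that make absolute
t/ha values incomparable across studies.

For studies that simulate both a climate-change and a
no-climate-change counterfactual world — so that non-climatic technological
trends can be removed — the published formula reads

```
YI = [{(Yf_cc − Yb_cc) − (Yf_ncc − Yb_ncc)}/Yb_cc − 1] × 100 .
```

Taken literally, two identical yield trends give `YI = −100%`, which
contradicts the formula's stated purpose: a world where climate change did
nothing should score zero. We treat the trailing `− 1` as a typographical
slip: `counterfactual_yield_impact()` defaults to the corrected form
(difference of trends over the climate-change baseline, ×100), under which
equal trends cancel exactly and a zero counterfactual trend reduces the
formula to the plain relative impact. The literal form is retained
(`mode = "literal"`) for audit, and every returned value records the mode
that produced it.

## Baseline correction

Impacts (and ΔT, ΔPr) are rescaled by linear interpolation in time:
divide by the study's year gap (future midpoint − study baseline midpoint)
to get a per-year rate, multiply by the gap from the reference midpoint
2005. The operation is the identity when the study baseline midpoint is
already 2005, is homogeneous in the value, and — an algebraic identity
worth testing numerically — leaves the per-year (hence per-decade) rate
unchanged, so it does not matter whether correction runs before or after
the per-decade division.

Period midpoints are integer years, `floor((start + end)/2)`; the
convention (half-years rounded down) is fixed here because corpora print
integer midpoint years (2020/2050/2080) without stating a rounding rule.
Year gaps below 1 year and warming denominators below 0.1 °C are flagged
undefined rather than divided — a degenerate denominator produces an
exploding ratio, not information. Flagged records are excluded from
summaries (never imputed as zero); both thresholds live in
`impact_config()`.

**Open question resolved:** published per-crop per-degree tables do not say
whether the denominator is local or global warming. The default here is
global warming from the 2001–2010 baseline (`dTg_2005`) — the quantity tied
to mitigation targets — with a configuration switch, and the basis is
stamped on every output row so downstream tables are self-describing.

Global warming is carried against two references (2001–2010 and
preindustrial 1850–1900) separated by a configurable offset, default
0.8 °C, taken from the printed relationship between the two scales.

## Adaptation pairing

Within a pairing key of (study, site, crop, scenario, future midpoint, CO₂
flag), each with-adaptation record is matched to the group's single
no-adaptation record; the adaptation potential is the percentage-point
difference of harmonized impacts. Groups with several no-adaptation records
are reported ambiguous and not paired — guessing a counterpart would
manufacture effect sizes. The CO₂ flag is part of the key so that
fertilization-on and -off runs never pair. ESM ensemble averaging runs
before pairing. The key is the finest the schema supports; a coarser
(country-level) key can be passed when a corpus was extracted at that
granularity. For the planting-time option, when a study tests several
planting dates only the best-yielding variant is retained (ties break to
the earliest variant label, deterministically).

## Covariate imputation

Missing `dTl_2005`, `dTg_2005` and `dPr` are filled by a random-forest
regressor: bootstrap-bagged CART trees, variance-reduction splits, minimum
node size 5, 500 trees by default, out-of-bag predictions for internal
validation. The deployment environment provides no forest package, so the
regressor is implemented in compiled code inside the package; it is
deterministic given its seed.

Candidate feature sets are compared by k-fold (default 10) cross-validated
RMSE and by out-of-bag explained variance (OOB R² × 100); the set with the
highest explained variance wins and is refit on all complete records. For
the local temperature rise the candidate pool holds four models, from the
full six-variable set (global rise, area-weighted current temperature,
latitude, longitude, future midpoint, scenario) down to the three-variable
reduced set (global rise, latitude, longitude); for precipitation change,
the pool includes the seven-variable set ending in current annual
precipitation. Categorical features are one-hot encoded with alphabetically
fixed level order.

Two design points deserve emphasis:

* **A categorical predictor is one predictor.** Feature subsampling draws
  whole predictors, not dummy columns; a selected categorical contributes
  all its one-hot columns to the split search. Counting dummy columns would
  hand models containing a many-level factor several times more draws per
  split and bias the model comparison for a reason unrelated to
  information content.
* **mtry defaults to all predictors** (randomness from the bootstrap
  alone), the regression default of the reference ensemble-tree stack.
  Under the classical `floor(p/3)` convention the comparison between a
  6-feature and a 3-feature candidate is decided by integer quantization of
  mtry (2 vs 1) rather than by the features themselves. With all predictors
  in scope at each split, an irrelevant feature can only add overfitting
  noise, which is exactly the signal the cross-validated comparison should
  detect. `mtry = "third"` and integer values remain available.

Imputation fills only records whose target is missing and whose model
features are all observed; everything else is returned bit-identical, and
unfillable rows are listed in a skip report. When several targets are
missing the order is global rise → local rise → precipitation change,
following the dependency structure of the feature sets. Records missing
both temperature covariates cannot be filled by either model (each is a
feature of the other) and are reported, not guessed.

## Climate fields

Climate normals are per-cell means of annual values over a window
(2001–2010 by default) on the standard half-degree grid, cell centers at
±0.25° + k·0.5°. Point extraction returns the containing cell's value;
coordinates exactly on a cell boundary resolve to the cell **north-east**
of the corner — the convention is arbitrary but fixed and documented,
because silent library-dependent tie-breaking is a classic
irreproducibility source. Country-level records get both a centroid
point extraction (`Tave`) and a harvested-area-weighted mean (`Tave_w`),
since a centroid can sit far from the growing areas of a large country.
Weighted means are `Σwv/Σw` over a cell mask; they are invariant to
uniform weight rescaling and collapse to point extraction for a single
cell.

Scenario CO₂ concentrations are linearly interpolated within tabulated
trajectories, with no extrapolation. The packaged trajectory table
(`inst/extdata/co2_trajectories.csv`) carries rounded representative
decadal values per scenario family; it is a synthetic stand-in adequate for
interpolation mechanics and the generator, not a redistribution of any
scenario database. Precipitation changes reported only as percentages are
converted with `ΔPr = rel/100 × Pr_base`.

Only CSV rasters are read: the deployment environment has no netCDF
reader, and grid ingestion is an adapter concern — tests and the generator
use small synthetic grids throughout.

## Distribution summaries and outliers

Summaries report n, extremes, mean, type-7 quantiles (linear interpolation
of order statistics — fixed so two runs of the pipeline agree to the bit),
standard deviation, moment-based sample skewness `m3/m2^1.5` and kurtosis
`m4/m2²`. Kurtosis is **excess** (normal → 0) by default and the convention
is echoed in every output row, because "large kurtosis relative to the
normal" claims are convention-dependent. Shape statistics are flagged
undefined below n = 3 or at zero variance.

The 1.5×IQR outlier rule is ambiguous in prose: fences can anchor at the
median (median ± 1.5·IQR — the whisker definition used in box-plot figure
captions of this literature) or at the quartiles (Tukey's fences). The
default is the median anchor, with Tukey available; sensitivity reports
state the rule used and report the removed count/percentage and the
mean/median shifts after removal. For a standard normal the two rules flag
about 4.3% and 0.70% respectively — the test suite checks both against
their closed forms.

## The synthetic generator: what it emulates, what it does not

`generate_corpus()` draws a corpus whose *composition* matches the
published coverage of a consolidated projection corpus: crop shares
(~52/26/17/3% for maize/wheat/rice/soybean — the printed rounded shares sum
to 0.98 and are renormalized proportionally), scenario families (80% CMIP5,
11% CMIP3), a 61% adaptation share, ~50% missing local warming, matched
pairs for 23% of records (pairs/records), heterogeneous baselines
(midpoints 1961–2005), future midpoints clustered at 2020/2050/2080, a
0.8 °C preindustrial offset, and ~5% of runs without CO₂ fertilization.

Its *response surface* is stated, not estimated:

```
dTl = dTg · (1 + 0.5·cos(2π·lat/180)) + ε_T,  ε_T ~ N(0, 0.1 °C)
YI  = b0 + b1·dTl·max(0, Tave − T_crit) + b2·log(ppm/370)·[CO₂]
      + b3·[adaptation] + crop_effect + skewed noise
```

with defaults chosen once: `b0 = 3`, `b1 = −0.5`, `b2 = 8`, `b3 = 9`
percentage points (between published mid- and end-century mean adaptation
potentials of 7.3 and 11.6), `T_crit = 12 °C`, noise sd 15% with
skew-normal shape −4 (left skew, matching the negative skewness of real
impact distributions), and crop effects maize −6, soybean −3, wheat −2,
rice 0 (ordered like published per-decade medians). `b1` is sized so the
noiseless surface never reaches the −100% floor: that keeps the exact
noiseless recovery of `b3` attainable, while with noise the floor clips
the deep tail — as the real corpus's span (exactly −100 at the low end)
suggests it should. Impacts are generated on the 2005 reference scale and
back-transformed to study-scale raw impacts and yields, so harmonization
is exercised nontrivially.

What a green recovery test establishes: the pipeline's algebra, pairing,
selection and imputation recover a known data-generating process of the
assumed shape at realistic sizes and noise levels. What it does not
establish: anything about real crop physiology, real adaptation efficacy,
or the behaviour of the method under structured missingness, reporting
bias, or spatially correlated errors — none of which the generator
emulates.

Two honesty notes on recovery limits. First, a forest imputer on a
noiseless smooth surface does **not** reach zero error: leaf means pool
neighbouring sites, so an approximation-bias floor remains; the noiseless
limit is asserted exactly only for the adaptation coefficient (pair
differences cancel everything but `b3`). Second, with a 3% crop share,
soybean's group median carries a sampling error larger than a 1-pp
generated gap; recovery tests assert the orderings the corpus can actually
identify (maize most negative, rice least) rather than a full rank order.

## Numerical and schema conventions

* Missing values are `""`, `"NA"`, `"n/a"` on read (configurable), never
  coerced to 0; set-valued text fields normalize missing to the empty
  string so CSV round-trips are exact.
* Column order on write is the canonical schema order; two writes of the
  same records are byte-identical.
* Deposited-layout headers bind to the canonical schema through a
  `column_mapping()` object (the published article does not print column
  names; they live in a separate metadata workbook, so the binding is
  configuration).
* xlsx is read via `readxl` when present; output is CSV only (no xlsx
  writer in the supported dependency set).
* ESM ensemble averaging takes arithmetic means of numeric fields within
  groups whose non-numeric fields must agree exactly; disagreement is an
  error, not a silent first-wins.
* The top-producer filter keeps, per crop, the smallest set of countries
  (descending production share) whose cumulative share reaches the
  coverage target (default 95%), and touches only grid-aggregated records.
* All stochastic components (generator, fold assignment, forests) are
  seeded; the forest uses its own RNG stream and fold assignment
  saves/restores R's RNG state.

## Known limitations

* No netCDF ingestion; CSV rasters only.
* IPCC-style regions come from a country-lookup fixture, not polygons;
  region assignment for sites near borders follows the country label.
* The imputer does not propagate imputation uncertainty (single
  imputation, as in the source workflow); downstream variances are
  conditional on the filled values.
* Counts of missing covariates always come from the data at hand — source
  publications of such corpora report mutually inconsistent missing-data
  counts, and no count is hard-coded anywhere.
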