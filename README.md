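# cropclim

Crop-simulation studies have projected climate-change impacts on yields for
four decades, but their results are heterogeneous: every study reports
impacts against its own baseline period, at its own sites, under its own
emission scenario, often omitting the local warming or precipitation change
that drove the simulation. `cropclim` implements, as a tested and reusable R
pipeline, the harmonization and meta-analysis computations needed to turn
such a corpus of maize, rice, soybean and wheat projections into a single
analysable effect-size dataset — and ships a synthetic-corpus generator with
known ground truth so that every stage is verifiable without downloading
anything.

## What it computes

**Relative yield impact.** The core effect size is the percent yield change
between a future and a baseline period,

    YI (%) = (Yf / Yb − 1) × 100,

with a counterfactual variant for studies that also simulate a
no-climate-change world (so technological yield trends cancel):

    YI (%) = [(Yf_cc − Yb_cc) − (Yf_ncc − Yb_ncc)] / Yb_cc × 100.

(The literal published form of the counterfactual carries a trailing "− 1"
that makes identical trends score −100%; both forms are available, the
corrected one is the default. See the methods vignette.)

**Baseline correction.** Impacts, local/global warming and precipitation
changes are linearly rescaled from each study's own baseline midpoint to the
common 2001–2010 reference (midpoint 2005):
`v × (future_mid − 2005) / (future_mid − base_mid)`.

**Normalized rates.** Per-decade (`YI / decades since 2005`) and per-degree
(`YI / ΔT`) impacts, with sub-threshold warming flagged undefined rather
than divided.

**Adaptation potential.** Matched with/without-adaptation simulation pairs
within a study/site/crop/scenario/period/CO₂ key; the potential is the
percentage-point impact difference.

**Covariate imputation.** Missing local warming (≈half the corpus),
global warming and precipitation changes are imputed with a random-forest
regressor (implemented in compiled code inside the package), choosing among
candidate feature sets by 10-fold cross-validated RMSE and out-of-bag
explained variance.

**Climate context.** Half-degree climate-normal grids (point extraction with
a fixed corner tie-break, harvested-area-weighted country means) and
scenario CO₂-concentration lookup by linear interpolation.

**Distribution summaries.** Quartiles, moment skewness/kurtosis, and
1.5×IQR outlier sensitivity (median-anchored fences by default, Tukey
fences as an option).

## Worked example

```r
library(cropclim)

g <- generate_corpus(generator_config(n_records = 5000, seed = 42))
h <- harmonize_records(g$records)

distribution_summary(h$YI_2005)
#>      n    min    q1 median   q3   max mean   sd skewness kurtosis
#>   5000 -73.77 -8.87   3.04 14.3 45.67 1.66 17.2    -0.59     0.43

pairs <- find_adaptation_pairs(h)$pairs
nrow(pairs); mean(pairs$potential)
#> 575 pairs, mean potential 8.55 pp   (generator truth: b3 = 9)

grouped_impact_table(h[!h$adaptation, ], "crop", metrics = "per_decade")
#>     crop    n median  mean skewness
#>    maize 1040  -0.67 -1.34    -1.32
#>     rice  328   0.31  0.23    -0.64
#>  soybean   61  -0.69 -0.98    -0.23
#>    wheat  518   0.25  0.06    -0.68

sensitivity_report(h$YI_2005)
#> 229 of 5000 removed (4.6%); mean shifts +1.81 pp, median +0.87 pp

fit <- fit_imputer(h, "dTl_2005", folds = 5, num_trees = 100, seed = 43)
fit$report$selected
#> "reduced3"  (dTg_2005 + lat + lon; CV RMSE 0.120 °C on a 0.1 °C noise floor)
```

The harmonized impact distribution is left-skewed (skewness −0.59) with a
hard floor at −100% (zero future yield); the mean pair potential recovers
the generator's adaptation coefficient; maize shows the most negative
per-decade median, rice the least, matching the generated crop effects; and
feature-set selection picks the three-variable reduced model, whose
cross-validated RMSE sits just above the known 0.1 °C noise floor.

## Command line

```sh
Rscript inst/scripts/cropclim-cli.R simulate  --n 5000 --seed 42 --out corpus.csv
Rscript inst/scripts/cropclim-cli.R ingest    --input corpus.csv --out clean.csv --reject-report rejects.csv
Rscript inst/scripts/cropclim-cli.R harmonize --input clean.csv --out harmonized.csv
Rscript inst/scripts/cropclim-cli.R impute    --input harmonized.csv --target dTl_2005 --out imputed.csv
Rscript inst/scripts/cropclim-cli.R adaptation --input harmonized.csv --out pairs.csv
Rscript inst/scripts/cropclim-cli.R summarize --input harmonized.csv --group crop --metrics per_decade,per_degree --out table.csv
```

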