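Package: cropclim
Title: Harmonization and Meta-Analysis of Projected Crop-Yield Climate Impacts
Version: 0.1.0
Authors@R: person("cropclim", "maintainers", email = "cropclim@example.org",
    role = c("aut", "cre"))
Description: Tools to harmonize heterogeneous crop-simulation studies of
    climate-change impacts on maize, rice, soybean and wheat yields into a
    single analysable corpus: relative yield-impact effect sizes with a
    counterfactual no-climate-change variant, linear rescaling of effect
    sizes to a common 2001-2010 baseline period, matched with/without
    adaptation pairing and adaptation potential, random-forest imputation of
    missing climate covariates with cross-validated feature-set selection,
    half-degree gridded climate-normal extraction with harvested-area
    weights, scenario CO2-concentration lookup, and distribution summaries
    with interquartile-range outlier sensitivity. Includes a synthetic-corpus
    generator with ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
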