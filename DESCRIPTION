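Package: coccotraits
Title: Trait Synthesis and Carbon Stock Estimation for Coccolithophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-taxon cell-size and cellular organic (POC) and
    inorganic (PIC) carbon distributions from heterogeneous multi-study
    measurements with full error propagation. Measurements reported as raw
    values, mean with standard error or standard deviation, min-max ranges,
    or bare means are reconstructed into replicate sets via zero-truncated
    normal sampling and Bayesian (Dirichlet-weighted) bootstrapping, merged
    across studies, and summarised with percentile confidence intervals.
    Gap-filling uses allometric Gamma generalised linear models of cellular
    carbon content against cell volume, with a ploidy covariate for
    inorganic carbon and training-set bootstrap ensembles for model
    uncertainty. Abundance observations are converted into taxon-specific
    carbon stocks and aggregated onto a 1-degree, 5-m, monthly grid.
    Includes a synthetic-data generator emulating the statistical structure
    of the input compilations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
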