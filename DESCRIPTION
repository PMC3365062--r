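Package: weevilrisk
Title: Multimodel Inference for Local and Landscape Drivers of Andean
    Potato Weevil Infestation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Information-theoretic screening of local (management, soil,
    geographic) and landscape predictors of Andean potato weevil
    (Premnotrypes spp.) tuber infestation in smallholder potato fields.
    Provides an area-weighted, square-root transformed infestation
    response; forward AIC-guided construction of a global model with a
    2.0-AIC tolerance stopping rule; exhaustive all-subsets evaluation;
    Akaike model and parameter weights; natural and shrinkage model
    averaging with unconditional standard errors; comparison of local-only,
    landscape-only and combined model classes; standardized predicted
    impacts; an insecticide-efficacy regression; and a permutation Moran's
    I correlogram for residual spatial autocorrelation. A calibrated
    synthetic field-record generator emulating the published study design
    makes every stage testable without the (undeposited) raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
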