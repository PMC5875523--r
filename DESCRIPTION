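Package: thoraxreg
Title: Deformable Registration and Validation for Pre- and Post-Treatment Thoracic CT/PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale Demons and Morphons deformable registration of
    pre-treatment and follow-up thoracic CT volumes, with landmark-based
    accuracy validation, a three-group registration-quality classifier,
    and Dice overlap analysis of fractional-SUVmax PET uptake contours.
    Includes a synthetic thorax phantom generator with known ground-truth
    deformations so every pipeline stage can be exercised end-to-end
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
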