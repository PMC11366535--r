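Package: wagyuIAT
Title: Carcass Cross-Section Image Traits and Genetic Parameters for Japanese Black Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image analysis of beef carcass cross-sections and for
    genetic evaluation of the resulting traits in Japanese Black (Wagyu)
    cattle. Generates synthetic carcass cross-section phantoms with exact
    ground truth; extracts per-muscle image-analysis traits (area, marbling
    percentage, coarseness index, new fineness index, inertia-axis
    thickness) and target-field intermuscular/subcutaneous fat traits; fits
    fixed-effects models of carcass unit price with marginal F tests and
    standardized partial regression coefficients; builds pedigree numerator
    relationship matrices and their sparse inverses with inbreeding; and
    estimates heritabilities and genetic correlations with single- and
    two-trait Bayesian animal models fitted by Gibbs sampling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    mgcv,
    igraph,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
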