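Package: neurohic
Title: Hi-C Contact-Map Normalization, Domain and Loop Calling, and
    Regulatory Linkage for Developing-Brain 3D Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for the 3D-chromatin analysis stack used in
    developmental brain Hi-C studies: sparse contact-matrix input/output, bin
    filtering and ICE (iterative correction) balancing, observed/expected
    normalization, A/B compartment profiles and their developmental dynamics,
    insulation-score TAD boundary detection, distance-stratified negative
    binomial loop calling and Weibull significant-interaction calling,
    ROSE-style super-enhancer stitching and interaction enrichment, SSIM
    (structural similarity) comparison of contact maps, GWAS SNP-to-gene
    linkage through promoter interactions, and fuzzy soft clustering of
    time-course expression. Ships a synthetic-data generator that plants
    ground-truth compartments, TADs, loops, super-enhancers, expression
    drivers and SNP links so every caller can be validated by recovery and
    calibration experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
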