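Package: methylBMI
Title: DNA-Methylation-Based Body Mass Index Prediction in Breast Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and applies a sparse DNA-methylation predictor of body
    mass index (DM-BMI) from Illumina 450K-style beta-value matrices. BMI is
    mapped through a piecewise log/linear trait transformation anchored at a
    healthy-BMI value, and the transformed trait is regressed on probe-level
    methylation with a lasso penalty selected by cross-validation. The
    package also estimates intra-sample adipose-tissue fraction by
    two-component reference-based deconvolution, characterizes predictor
    CpGs (genomic category distributions, paired differential methylation,
    correlation screens), computes formula-level immune and
    immunotherapy-response scores (tumor mutation burden, interferon-gamma
    and antigen-presentation signatures), and ships a synthetic-cohort
    generator with full ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
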