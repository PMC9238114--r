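Package: partbias
Title: Simulation and Correction of Sex-Differential Participation Bias in
    Genetic Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate study populations in which genotypes and
    binary traits drive study participation through a logit model, to
    quantify the collider (selection) bias this induces in sex GWAS,
    trait GWAS and Mendelian randomization on the participant subsample,
    and to apply and verify the stratify-then-meta-analyze correction:
    sex-stratified GWAS combined by fixed-effects inverse-variance
    meta-analysis. Includes an exact enumeration oracle for the
    post-selection sex-genotype association under the logit participation
    model, its rare-participation closed form, and reproducible scenario
    sweep experiments over participation-rate grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
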