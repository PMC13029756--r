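Package: agevarmr
Title: Age-Varying Genetic Effects from Age-Stratified GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects SNP-by-age interaction effects from age-stratified
    genome-wide association summary statistics by per-SNP fixed-effects
    meta-regression on mean stratum age, and propagates the interaction
    slopes into two-sample Mendelian randomization, including a modified
    inverse-variance weighted estimator in which each variant's age slope
    replaces its exposure association. Also provides a synthetic
    individual-level cohort generator, age-stratified association scans with
    LD clumping and power projection, a collider/selection-bias simulation
    study, and repeat-assessment attendance analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
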