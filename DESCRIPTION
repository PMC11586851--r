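Package: rfiherd
Title: Genomic Evaluation of Residual Feed Intake in Dairy Herds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Phenotype derivation and genomic evaluation of residual feed
    intake (RFI) in dairy cattle. Derives heifer and lactating-cow RFI from
    daily feed intake, milk and body-weight records (energy-corrected milk,
    outlier screening, within-trial and across-trial regressions), builds
    pedigree (numerator) and VanRaden genomic relationship matrices with
    marker quality control, estimates variance components by average
    information REML under univariate and bivariate animal models, performs
    two-step GBLUP with indirect prediction and reliability approximation for
    non-phenotyped animals, and analyses prediction cohorts (relative-group
    reliability decay, close-relative counts, power-curve regression,
    heifer-to-cow efficiency re-ranking). Includes a synthetic herd generator
    (multi-generation pedigree, gene-dropped genotypes, daily trait
    trajectories with injected outliers) so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
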