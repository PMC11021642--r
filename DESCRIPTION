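Package: mzewas
Title: Epigenome-Wide Association and Causal Inference for Discordant
    Monozygotic Twin Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for epigenome-wide association
    studies (EWAS) of a continuous trait in trait-discordant monozygotic twin
    pairs, built around reduced representation bisulfite sequencing (RRBS)
    count data.  Provides RRBS quality control (coverage capping, low-signal
    site filtering, beta to M-value transformation), reference-free
    cell-composition surrogates via feature-selected principal components,
    per-CpG generalized estimating equations with exchangeable within-pair
    working correlation and robust sandwich inference, ICE FALCON bidirectional
    causal inference from nested self/co-twin regressions, autocorrelation-
    adjusted Stouffer-Liptak region calling for differentially methylated
    regions, nearest-gene annotation, and methylation-expression correlation.
    A fully parameterised monozygotic-twin cohort simulator with planted
    causal, reverse-causal and confounded CpGs supports power estimation and
    ground-truth validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
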