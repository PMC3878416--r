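Package: metphase
Title: Design and REML Analysis of Multi-Phase, Multi-Environment Phenotype Screens
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing high-throughput phenotype
    screens that span a field phase and a laboratory phase, repeated across
    environments (trials). Generates spatial row-column field designs with
    replicate blocks and partially replicated (p-rep) 96-well plate designs
    that re-randomise field samples; simulates phenotype tables from a
    declared variance-component structure; fits linear mixed models by
    sparse REML (Henderson mixed-model equations) with per-trial residual
    variances and an optional cross-trial genetic covariance; and derives
    EBLUPs, prediction error variances, generalized heritability,
    likelihood-ratio tests, cultivar rankings and cross-trial concordance
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
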