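Package: semifieldgp
Title: Genomic Prediction with Neighbor and Spatial Effects for Semi-Field Row Trials
Version: 0.1.0
Authors@R:
    person("Semifield", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genetic analysis of row-based semi-field trials of
    winter wheat: VanRaden method-1 genomic relationship matrices, GBLUP
    mixed models with direct and indirect (neighbor) genetic effects and a
    running-sum spatial field with virtual border rows, average-information
    REML estimation of variance components, line-mean heritability and
    variance partitioning, leave-one-line-out genomic prediction with
    accuracy and inflation statistics, a minirhizotron root-image editing
    pipeline, and a synthetic-data generator emulating the facility design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
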