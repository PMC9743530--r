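Package: CellCapsule
Title: Interpretable Masked Capsule Networks for Single-Cell Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains an interpretable capsule-network classifier on single-cell
    RNA-seq expression profiles. One encoder network per cell type produces a
    primary capsule, and an identity mask applied to the coupling coefficients
    during dynamic routing enforces a one-to-one correspondence between primary
    capsules and type capsules, so the model can be read out directly: averaged
    coupling coefficients give a diagonal type-association heatmap, and principal
    component analysis of the encoder weight columns ranks genes by their
    contribution to each type. Because type-capsule lengths are unnormalized
    class probabilities, the trained model also scores non-standard samples:
    under-differentiated progenitors receive uniformly low probabilities whose
    maximum orders cells pseudo-temporally along each lineage, and doublets
    receive two high probabilities and are flagged. Includes a negative-binomial
    synthetic-data generator with planted markers, differentiation coordinates
    and doublet pairs, readers for dense and MatrixMarket expression formats,
    model persistence, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
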