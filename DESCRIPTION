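Package: stesh
Title: Multi-View Graph Convolutional Autoencoder for Spatial Domain Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies spatial domains in spatial transcriptomics data by
    integrating gene expression, spatial coordinates and histology-image
    morphology. Builds spatial, expression and morphological neighbor graphs,
    learns a fused low-dimensional spot embedding with a multi-view graph
    convolutional autoencoder (attention-based view fusion, negative-binomial
    reconstruction, graph-consistency and neighborhood-regularization losses,
    trained with Adam on a built-in reverse-mode autodiff core), and clusters
    the embedding into spatial domains with Gaussian mixture models. Includes
    a synthetic-data generator (planted domains, negative-binomial counts,
    rendered histology) so the full pipeline is testable offline, plus
    ARI/NMI/FMI clustering metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    mclust,
    jsonlite,
    png,
    EBImage,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
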