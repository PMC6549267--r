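Package: msinet
Title: Molecular Colocalization Networks for Mass Spectrometry Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Groups m/z-images of a mass spectrometry imaging (MSI)
    experiment into molecular communities. Pairwise Pearson correlation of
    m/z-image pixel vectors yields a similarity matrix, which is sparsified
    by a data-driven threshold chosen from quantitative graph properties
    (edge count, average clustering coefficient, global efficiency)
    combined by PCA weighting. Communities are detected with a
    leading-eigenvector modularity method initialized from connected
    components. The package also renders community maps
    (maximum-projection and averaging modes) and PCA RGB overview maps,
    builds a collapsed community graph with hybrid edges for interactive
    viewers, and ships a synthetic nine-Gaussian benchmark generator so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    data.table,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: MassSpectrometry, ImagingMassSpectrometry, Network, Clustering,
    GraphAndNetwork, Visualization
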