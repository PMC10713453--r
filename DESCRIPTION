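Package: laminator
Title: Laminar-Window Phenotyping of Multiplexed Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial phenotyping toolkit for multiplexed immunofluorescence
    (4i) images of laminated tissues such as retinal organoid sections.
    Provides pixel-level multiplexed tissue unit (MTU) clustering via a
    self-organizing map with graph-community metaclustering, the laminar
    window algorithm (contour-anchored 100 x 1000 px windows oriented
    against the tissue distance transform), FFT profile distances combined
    by a DISTATIS compromise, diffusion pseudotime and maturation scoring
    over laminar windows, radial cell-neighborhood profiling, and
    kernel-density spatial feature correlation. Ships a synthetic
    organoid-phantom generator with analytic ground truth so the whole
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    igraph,
    MASS,
    RANN,
    uwot,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
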