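Package: polconf
Title: Comparative Conformational Dynamics of DNA Polymerase Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of conformational dynamics in multidomain proteins,
    built around the open/ajar/closed transition of A-family DNA polymerases.
    Provides interconformer principal component analysis of crystal-structure
    ensembles with projection of molecular dynamics trajectories, Calpha
    distance-fluctuation (coordination propensity) matrices and local
    flexibility profiles, the multidomain Energy Decomposition Method
    (eigen-analysis of residue-pair nonbonded interaction-energy matrices,
    essential-eigenvector selection, folding-matrix symbolization, energetic
    domain clustering, stabilization profiles and hotspot extraction),
    FRET-proxy inter-residue distance series, and synthetic generators with
    planted ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
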