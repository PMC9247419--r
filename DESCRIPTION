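Package: connallom
Title: Allometric Scaling of White-Matter Connectivity Across Primate Brains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Comparative connectomics toolkit for studying how white-matter
    network organization scales with brain size across species. Provides
    phylogenetic generalized least squares (PGLS) regression with Pagel's
    lambda under a Brownian-motion model of trait evolution, random
    evenly-dispersed parcellation of triangulated cortical surfaces,
    construction of region-by-region connectomes from streamline endpoint
    tables, binary graph metrics (density, characteristic path length,
    clustering coefficient, degree, betweenness, rich club) normalized
    against degree-preserving rewired null models, brain-size-normalized
    connection-length distributions, a homotopic connectivity-asymmetry
    statistic with rank-based weight normalization and a permutation null,
    and a synthetic-data generator (ultrametric trees, Brownian traits with
    configurable allometric exponents, mirrored two-hemisphere connectomes
    with distance decay) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
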