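Package: twinconn
Title: Genetic and Environmental Decomposition of Brain Functional
    Connectivity in Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical twin design applied to resting-state
    functional-connectivity (FC) phenotypes. Builds significance-masked
    weighted and binarized FC matrices from region-of-interest BOLD time
    series, extracts link-, node- and network-level graph features (degree,
    signed strengths, clustering, local and global efficiency, betweenness,
    characteristic path length, density, Louvain modularity), estimates
    zygosity-specific intra-pair partial correlations adjusted for age and
    sex, gates each feature into epistasis / ADE / ACE scenarios from the
    rMZ/rDZ ratio, computes Falconer variance decompositions with broad-
    and narrow-sense heritability, compares correlations with one-sided
    Fisher-Z tests under Bonferroni correction, summarises effects within
    resting-state networks, and performs Monte Carlo power analysis for
    twin-pair correlation designs. A synthetic-cohort generator with known
    A/C/D/E variance structure makes the whole pipeline testable without
    access to raw imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
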