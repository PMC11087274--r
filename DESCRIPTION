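Package: nanoreactr
Title: Nanoreactor Active Learning for Reactive Interatomic Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of nanoreactor active learning for
    condensed-phase reactive chemistry of C, H, N and O. Provides periodic
    atomic configurations with minimum-image geometry, builders for random
    carbon boxes and packed molecular mixtures, oscillating temperature and
    density schedules, a Langevin (BAOAB) molecular dynamics engine with
    on-the-fly density control, Behler-Parrinello-style symmetry-function
    descriptors, an ensemble of random-feature ridge regressors with
    query-by-committee uncertainty selection, a pluggable labeler with a
    built-in toy reactive potential, and a molecular-graph trajectory
    analyzer (bond perception, isomorphism-based species census, ring
    census, species tracking and ignition delay times). Extended-XYZ is the
    interchange format throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
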