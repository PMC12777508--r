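Package: gquadms
Title: Native Mass Spectrometry Analysis of Tetramolecular RNA G-Quadruplexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for native electrospray mass spectrometry of
    tetramolecular RNA G-quadruplexes: exact monoisotopic mass and m/z
    bookkeeping for multimeric RNA-cation species, isotope pattern
    computation, enumeration and classification of collisionally activated
    dissociation (CAD) backbone fragments (a/c/w/y series) and neutral
    losses, stoichiometry-weighted species quantification from centroided
    peak lists, breakdown-curve construction with E50 (energy of 50%
    quadruplex dissociation) fitting, a combinatorial tetrad-topology model
    scoring strand-separation pathways, UV melting curve fitting with
    linear baseline plus one or two sigmoids, and seeded synthetic-data
    generators emulating ESI spectra, CAD energy series, and melting
    traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
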