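Package: xlensemble
Title: Ensemble Refinement of Protein Complexes from Cross-Linking Mass
    Spectrometry Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rigid-body simulated-annealing refinement of two-subunit protein
    complexes against chemical cross-linking mass spectrometry (CXMS) distance
    restraints. Supports linker-specific C-alpha to C-alpha upper bounds (BS3,
    BS2G, PDH), square-well restraint potentials, ensemble-averaged ambiguous
    restraints for transient and fleeting complexes, C2 symmetry restraints for
    homodimers, minimal ensemble-size selection, cross-link compatibility and
    jackknife analysis, isotope-mixing intermolecular assignment analytics,
    solvent-accessible surface distances, atomic probability maps, and
    spherical-coordinate projections with density-based clustering of
    conformer positions. Includes a generator of synthetic benchmark systems
    with planted binding poses and a consistent cross-link set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
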