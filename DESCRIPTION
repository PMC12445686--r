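Package: qdhkit
Title: Analysis of Quadruplex-Duplex Hybrid Structures and Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the structural analysis of DNA quadruplex-duplex
    hybrids (QDHs) and their complexes with intercalating G-quadruplex
    ligands. Builds idealized three-quartet hybrid models from a declarative
    fold description, detects G-quartets and Watson-Crick pairs from
    coordinates via Hoogsteen hydrogen-bond graphs, engineers NMR-style
    distance/torsion/planarity restraint sets from NOE volume tables
    (isolated spin-pair r^-6 calibration), measures junction geometry
    (rise, groove width, ring tilt, ligand angular-position pseudotorsion),
    reconstructs free-energy profiles from well-tempered metadynamics bias
    on a periodic collective variable, and fits two-state thermal melting
    curves with sloping baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
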