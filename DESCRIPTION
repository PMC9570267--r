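Package: deskqsar
Title: Conceptual-DFT Reactivity Descriptors, Drug-Likeness Screening and
    Small-n QSAR for Thiouracil-Based Anticancer Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale cheminformatics pipeline for candidate anticancer
    compounds: benchmarking of quantum-chemistry methods against X-ray bond
    lengths via a mean-absolute-deviation percent metric; global reactivity
    descriptors (ionization potential, electron affinity, energy gap,
    electronegativity, hardness, softness, chemical potential, electrophilicity,
    nucleophilicity) from frontier-orbital energies; Lipinski, Veber and
    Golden-Triangle drug-likeness screening; conversion between docking binding
    free energies and inhibition constants under the AutoDock convention; and
    multilinear-regression QSAR with four IC50 response transforms, explicit
    minimum-norm handling of underdetermined small-n fits, and forward stepwise
    selection. Ships plain-text fixtures for a four-compound thiouracil-based
    dihydroindenopyridopyrimidine panel plus etoposide, and a seeded synthetic
    compound generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
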