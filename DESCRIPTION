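Package: consite
Title: Consensus Ligand-Binding Site Mapping and Molecular Evolution of
    Peptide Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps a consensus ligand-binding site onto a reference
    G-protein-coupled receptor model by superposing an ensemble of
    ligand-bound receptor structures (Kabsch least-squares fitting),
    transferring each ligand into the reference frame, detecting
    side-chain/ligand heavy-atom contacts, and aggregating per-residue
    contact frequencies into binned consensus tables. Companion
    sequence-evolution tools relate the mapped site to receptor-family
    history: reference-numbered multiple alignments, position frequency
    matrices, per-column conservation profiles suitable for B-factor
    annotation of structures, neighbor-joining phylogenies, and
    receptor-ligand residue covariation screens (Cramer's V with
    permutation tests). A synthetic-data module generates seven-helix
    bundle ensembles with planted pockets and receptor/ligand sequence
    families with planted conservation and covariation, so every stage
    is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
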