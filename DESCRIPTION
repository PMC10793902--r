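Package: lgn
Title: Ligand-Aware Graph Network Scoring of Protein-Ligand Binding Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based prediction of protein-ligand binding affinity with a
    fusion graph neural network. A protein-ligand complex is represented twice: as a
    complex graph over all pocket and ligand heavy atoms (41-dimensional node and
    21-dimensional edge features, covalent plus distance-based intermolecular edges)
    encoded by attention-weighted message passing with gated recurrent unit updates,
    and as a ligand-only covalent graph (27-dimensional node features) encoded by a
    graph isomorphism network. Protein-ligand interaction fingerprints (a
    residue-by-interaction-type count vector and extended-connectivity atom-type pair
    counts) and a circular ligand fingerprint can be fused through a single linear
    layer. Includes readers for PDB pockets, SDF/mol2 ligands and affinity index
    files, similarity-controlled dataset splitting (protein sequence identity, ligand
    and interaction fingerprint Tanimoto), k-fold cross-validation, a bagging
    ensemble, and a synthetic complex generator with a planted affinity signal for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ChemmineR,
    bio3d,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
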