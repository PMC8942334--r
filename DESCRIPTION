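Package: structphylo
Title: Structure-Based Phylogenetics of Helical Protein Domains
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers evolutionary relationships between alpha-helical protein
    domains directly from their 3D coordinates. Reads PDB-format structures,
    detects helices from Calpha geometry, performs rigid and flexible
    (hinge-allowing) structural alignment by chaining aligned fragment
    pairs, converts pairwise similarity scores into distances, and builds
    distance-matrix phylogenies (UPGMA, neighbor joining, Fitch-Margoliash)
    with majority-rule consensus. Also measures inter-block hinge rotations,
    maps ligand-contact residues and sequence motifs, and provides a fully
    seeded synthetic-structure generator for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
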