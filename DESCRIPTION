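Package: descalign
Title: Multiple Protein Structure Alignment with Local Structure Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multiple alignments of protein structures from local
    structure descriptors: small spatial neighborhoods of each residue built
    from residue contacts and five-residue backbone elements merged into
    segments. Pairs of similar descriptors between structures act as local
    pairwise alignments; the largest consistent ensemble is found by maximum
    clique search (exact branch-and-bound and a Motzkin-Straus replicator
    heuristic) with branch-and-bound conflict resolution. Multiple alignments
    are seeded by stochastic neighbor-joining guide trees and refined with a
    steady-state evolutionary algorithm with gradual extension of the search
    space, scored by a tension measure based on local element RMSDs with
    rotation-angle augmentation of disconnected regions. Includes alignment
    quality measures (fraction of correctly aligned columns and residue
    pairs), Dolan-More performance profiles, and a synthetic structure-family
    generator with known ground truth. No global superposition is imposed, so
    hinge motions, segment swaps and circular permutations can be aligned.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
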