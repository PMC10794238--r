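Package: tcsevol
Title: Conservation, Coupling and Structure-Oriented Sequence Evolution for
    Two-Component Signaling Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two complementary analyses of the bacterial two-component
    signaling (TCS) system formed by a histidine kinase (HK) and its cognate
    response regulator (RR). The family track computes first-order
    (relative-entropy) conservation, hydrophobic preference and second-order
    coupling conservation from a paired DHp/Rec multiple sequence alignment,
    fits the power-law magnitude-frequency spectrum of couplings, and
    provides a random-sequence null. The structure track evaluates
    Miyazawa-Jernigan contact energies on intra- and inter-domain contact
    maps, residue-level frustration indices against composition decoys,
    decoy-ensemble stability and funnel (Z-score) fitness measures, and a
    rank-wheel genetic-algorithm simulation of sequence evolution under
    folding-only and folding-plus-binding selection. Synthetic generators
    (planted-signal alignments, toy lattice structures, rewired folding
    decoys and rigid-body binding decoys) make every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
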