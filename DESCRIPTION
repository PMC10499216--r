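Package: equippis
Title: E(3)-Equivariant Graph Neural Networks for Protein-Protein
    Interaction Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Partner-independent prediction of protein-protein interaction
    (PPI) sites from a single-chain structure using an E(3)-equivariant
    graph neural network. Builds a residue contact graph from C-alpha
    coordinates (14 Angstrom cutoff, minimum sequence separation 6),
    computes a 118-channel per-residue feature matrix from sequence
    profiles, language-model embeddings, secondary structure, solvent
    accessibility, local backbone geometry, residue orientation, convex
    hull surface area and contact counts, and classifies every residue
    through a stack of equivariant graph convolution layers whose
    predictions are invariant under rotation, translation and reflection
    of the input coordinates. Includes a training loop with Adam and
    cosine-annealed learning rate, confusion-matrix and ranking metrics,
    a paired resampling significance procedure, and a synthetic-complex
    generator for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    nortest,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
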