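Package: latentmol
Title: Molecular Representation Learning with a Graph Encoder and a SMILES
    Decoder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale molecular foundational-model toolkit. A graph
    neural encoder with global attention pooling maps molecules to 1D
    representation vectors and is pre-trained by projecting representation
    pairs onto multi-component similarity labels (conformational-space
    pharmacophore similarity over nested strain-energy windows plus
    fingerprint similarities). An autoregressive Transformer decoder
    reconstructs SMILES from the same representation space with a
    frequency-weighted cross-entropy loss and Gumbel-max sampling.
    Property heads, similarity screening with early-recognition metrics,
    stochastic propagation, directed migration and chemical fusion operate
    directly on the representation space. Includes a deterministic
    fragment-grammar fixture generator so everything is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: python (>= 3.8) with rdkit, on the PATH
Config/testthat/edition: 3
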