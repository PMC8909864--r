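Package: molgen
Title: Scaffold-Focused Molecule Generation with SMILES Language Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Character-level SMILES language modelling for de novo design of
    scaffold-focused small-molecule libraries. Provides a two-layer LSTM
    next-character model fitted with smiles_lm(), temperature-controlled
    autoregressive sampling seeded by rooted scaffold spellings (SMILES
    strings that end at a chosen attachment atom so that generated characters
    grow a substituent there), transfer learning onto small target-specific
    corpora with selective layer freezing, library quality metrics (validity,
    uniqueness, and MACCS/Tanimoto novelty), physico-chemical descriptor and
    synthetic-accessibility/drug-likeness profiling, 2-D chemical-space
    embeddings, and a MACCS-fingerprint multilayer-perceptron activity
    discriminator that closes the design-test loop. Chemistry primitives are
    computed with RDKit through a bundled helper invoked via the system
    python.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
SystemRequirements: python (>= 3.8) with rdkit, numpy and scikit-learn on
    the PATH for chemistry and embedding primitives
Config/testthat/edition: 3
RoxygenNote: 7.3.3
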