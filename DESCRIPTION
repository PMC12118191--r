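Package: koffkit
Title: Binding-Kinetics Modeling from Residue Interaction-Energy Fingerprints
Version: 0.1.0
Authors@R: person("koffkit", "developers", role = c("aut", "cre"),
    email = "koffkit@example.org")
Description: Predicts protein-ligand dissociation rate constants (as
    pkoff = -log10 koff) from equilibrium complex structures. Computes
    per-residue van der Waals and electrostatic ligand-protein interaction
    energies (COMBINE-style descriptors), applies a four-step descriptor
    pretreatment (positive-energy truncation, standard-deviation filtering,
    optional standardization, PCA), and regresses pkoff with a variational
    Bayesian neural network plus seven baseline regressors behind one
    fit/predict contract. Includes ranked 4:1 splitting, leave-one-out
    cross-validation with twelve regression statistics, dataset quality
    checks, a Bronsted-Evans-Polanyi validity fit, a synthetic-complex
    generator for end-to-end testing, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    quadprog,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
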