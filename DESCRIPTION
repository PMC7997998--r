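Package: fraglogp
Title: Fragment-Based Lipophilicity Prediction and Membrane-Permeability
    Classification of Fluorescent Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a 319-feature fragment fingerprint for small molecules
    (Hall-Kier electrotopological atom-type counts plus a curated SMARTS
    fragment vocabulary), trains a small feedforward neural network that maps
    the fingerprint to the octanol/water partition coefficient (LogP), and
    classifies fluorescent probes as cell-permeant or impermeant with a
    LogP >= 1 threshold rule. Includes a from-scratch Wildman-Crippen SLogP
    baseline, dataset-assembly utilities with canonical-SMILES deduplication,
    descriptor benchmarking statistics (per-class threshold fractions,
    accuracy, Welch t-tests), and synthetic-data generators for end-to-end
    testing without external downloads. Molecule handling is built on
    ChemmineR/ChemmineOB (OpenBabel).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
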