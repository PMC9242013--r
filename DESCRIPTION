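Package: deltabarrier
Title: Delta-Machine-Learning Prediction of Reaction Barriers from
    Semi-Empirical Quantum Chemistry
Version: 0.1.0
Authors@R:
    person("deltabarrier", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting DFT-quality free-energy activation
    barriers of C-C bond forming nitro-Michael additions from cheap
    semi-empirical quantum mechanics (SQM) calculations corrected by
    machine learning. Parses quantum-chemistry output (geometries,
    energies, harmonic frequencies, Mulliken charges), computes
    quasiharmonic Gibbs free energies and bimolecular activation
    barriers, extracts interpretable physical-organic descriptors
    (PEOE charges, EState indices, Sterimol parameters, percent buried
    volume, solvent-accessible surface area), assembles and
    preprocesses feature tables, trains and evaluates seven regressor
    families in direct and delta-learning modes, and quantifies
    SQM-vs-DFT transition-state geometry agreement (Kabsch RMSD,
    bond-forming distances, van der Waals contacts). Includes a
    deterministic synthetic-data generator so the full pipeline is
    testable without any electronic-structure software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
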