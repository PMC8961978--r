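Package: circomp
Title: Modular Genetic-Circuit Models via Hierarchical SBML Level 3 Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds modular models of synthetic gene circuits in which
    transcription units, mRNA pools, and a protein-degradation pool are
    independent submodels wired together through ports and cell-level
    connecting species, following the SBML Level 3 hierarchical model
    composition ('comp') scheme. Circuits are serialized to one XML file per
    submodel plus a main cell file, flattened to a single reaction network,
    and simulated as deterministic ODE systems with mass-action and
    non-cooperative Hill kinetics. Ships turn-key models of two yeast NOT
    gates built on ClpXP-mediated degradation of an ssrA-tagged reporter
    (one galactose-responsive, one beta-estradiol-responsive), with
    steady-state ON/OFF analysis, input titration sweeps, and seeded
    multi-start parameter optimization of the gate ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
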