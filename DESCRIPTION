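Package: tgfbms
Title: Multi-Scale Simulation of TGF-beta Signaling from Smad Pathway to
    Breast Tissue and Bone Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic multi-scale models of transforming growth factor
    beta (TGF-beta) in early breast cancer: an eight-variable Smad pathway
    ODE system and its order reduction, a per-phenotype cellular model of
    autocrine/paracrine ligand-receptor exchange through a shared diffusive
    region, a phenotype-structured tissue population model with TGF-beta
    modulated proliferation and apoptosis, a loose cellular-tissue coupling
    by time-averaged ligand influx, and a delay differential equation model
    of a bone multicellular unit perturbed by metastatic cancer cells.
    Includes variance-based first-order sensitivity analysis, a
    gene-expression fixture generator, delimited trajectory writers, and a
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
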