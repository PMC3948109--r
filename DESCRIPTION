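Package: tagelucidator
Title: Structure Elucidation of Short-Chain Triacylglycerides from
    Tandem and Ozone-Induced Dissociation Mass Spectra
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multi-stage pipeline for assigning the structures of
    triacylglycerides (TAGs) that carry one long-chain and two
    short-chain fatty acyl substituents, as found on the cuticle of
    desert Drosophila males. Stages are exact-mass elemental and
    acyl-composition search on alkali-metal adduct ions, assignment of
    acyl chains and glycerol backbone (sn) positions from
    collision-induced dissociation (CID) neutral losses, localization
    of carbon-carbon double bonds and scoring of cis/trans geometry
    from ozone-induced dissociation (OzID) aldehyde/Criegee product
    pairs, and downstream quantification (reference-peak and TLC band
    normalization) and mate-choice statistics (preference scores with
    exact tests). A seeded synthetic-spectrum generator provides
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
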