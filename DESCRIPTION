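Package: spinesim
Title: Dendritic Spine Morphometry and Two-Layer Neuron Information Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of dendritic spine morphology from
    serial-section reconstruction tables (spine head volume, postsynaptic
    density area, neck dimensions, per-dendrite densities, axon-coupled spine
    and endoplasmic-reticulum statistics), a normality-gated statistical
    workflow with Bonferroni-corrected pairwise comparisons, an event-driven
    two-layer leaky integrate-and-fire neuron model with lognormal synaptic
    weights, mutual-information analysis of input-to-spike information
    transfer over binarized 5-ms bins, quantification of glutamate-uncaging
    EPSP trace sets, and a seeded synthetic-data generator that emulates the
    per-region summary distributions so that the whole pipeline is testable
    without any imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
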