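Package: gutGEM
Title: Constraint-Based Metabolic Modeling of Gut Anaerobes and Their
    Communities
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating and simulating genome-scale metabolic
    models of gut bacteria. Provides S4 containers for stoichiometric
    models, growth media, flux solutions and multi-species community
    models; flux balance analysis (FBA), parsimonious FBA, flux
    variability analysis and single gene/reaction essentiality on a
    built-in linear-programming core; thermodynamic reaction-
    directionality curation from transformed Gibbs energies;
    energy-generating-cycle screening and ranked gap-reaction
    integration; transcriptome contextualization (CPM thresholding and
    GIMME) with pruning of inactive reactions; abundance-weighted
    community assembly with cross-feeding inference; SBML (Level 3,
    FBC) and TSV model I/O; and seeded generators for synthetic
    anaerobe and community test scenarios with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports:
    Matrix,
    stats,
    utils,
    xml2,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
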