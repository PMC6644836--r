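Package: fuzzypath
Title: Boolean Network Compilation and Fuzzy-Logic Simulation of Drug
    Perturbation on Reaction-Based Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts reaction-centric pathway descriptions (reactions with
    inputs, catalysts, activators, inhibitors and outputs; complexes; entity
    sets) into Boolean networks, simulates them with constrained fuzzy logic
    (continuous states in [0,1], synchronous updates, attractor detection and
    trace expansion), and scores per-entity drug impact by comparing reference
    and drug-perturbed simulations. Drug-target binding assay values (KD, Ki,
    IC50, EC50, in nM) are mapped to perturbation strengths through a piecewise
    affinity-to-strength function. Also provides drug-target evidence table
    reading and filtering, pathway enrichment by binomial test with
    Benjamini-Hochberg FDR control, and overlay of drug-target edges onto a
    functional-interaction subnetwork of frequently mutated genes. Deterministic
    fixture generators make the full pipeline testable without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
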