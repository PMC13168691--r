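Package: telosim
Title: Telomere Shortening, Replicative Senescence and Telomere-Driven
    Genome Instability: Simulation and Inference
Version: 0.1.0
Authors@R:
    person("telosim", "developers", email = "telosim@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative study of replicative senescence
    driven by the shortest telomere in telomerase-negative budding yeast.
    Implements a stochastic single-lineage model of the DNA end-replication
    problem (per-division overhang-sized shortening of one telomere out of
    two), an inducible endonuclease module that truncates one telomere to a
    defined length during a galactose window, and a Type A / Type B
    senescence state machine with a near-deterministic shortest-telomere
    threshold.  Provides calibration of the per-division cut probability,
    a threshold-length scan against observed senescence-onset medians, and
    ordered-lifespan envelope comparison.  A sequence-analysis component
    generates and analyses single-molecule reads of degenerate TG(1-3)
    telomeric repeats: end-position histograms, shortening-step inference,
    telomerase-extension simulation on the RNA template, and
    divergence-point detection.  A fluctuation-analysis component simulates
    Luria-Delbruck experiments and estimates mutation and gross chromosomal
    rearrangement rates by the p0 method and the Ma-Sandri-Sarkar maximum
    likelihood, with profile-likelihood confidence intervals, fold changes
    and dual-marker event classification.  Every input the pipeline
    consumes can be emulated by seeded synthetic-data generators with
    ground-truth sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
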