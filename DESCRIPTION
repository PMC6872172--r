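Package: subsweep
Title: Selective Sweep Detection and Classification in Subdivided Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulators of adaptation in
    subdivided populations (a single-site trajectory simulator for two- and
    three-deme models and an infinite-sites simulator of a 600-kb genomic
    region with recombination, migration and co-dominant selection), a panel
    of site-frequency-spectrum and haplotype summary statistics for sliding
    window sweep scans (Tajima's D, Fay and Wu's H, H1/H12/H2/H1, iHS, nSL,
    simplified SweepFinder-style CLR and XP-CLR, Hudson FST), neutral
    background threshold calibration at fixed false positive rates, and a
    two-stage boosted-tree protocol that first detects sweeps and then
    classifies them as hard or soft, exposing the temporal and spatial
    misclassification phenomena that arise when the training stage or the
    demographic model mismatch the data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
SystemRequirements: Python with msprime (optional, for the coalescent
    neutral-background backend)
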