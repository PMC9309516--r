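Package: frpkit
Title: Fragment Recruitment Plots and Reference-Based Species Presence
    Calling for Shotgun Metagenomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-based taxonomic profiling of shotgun metagenomes of
    plant-surface (carposphere and phyllosphere) microbial communities.
    Implements sliding-window quality trimming of reads, depletion of
    host-plant reads, best-hit fragment recruitment of reads to a curated
    genome manifest, per-genome read-based average nucleotide identity (ANI)
    and coverage-uniformity (RSD) statistics, rule-based species presence
    calls with identity-band reporting and two-cloud detection, abundance
    rollups, community diversity statistics (Simpson, Pielou, Bray-Curtis,
    PERMANOVA, SIMPER, PCA), and fragment recruitment plots. A seeded
    synthetic community generator produces toy genomes, reads with
    configurable divergence, host contamination, and matching alignment
    tables with truth labels, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Biostrings,
    IRanges,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
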