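Package: wsstrack
Title: Window-Based SNV Similarity Strain Tracking for Fecal Microbiota
    Transplant Metagenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strain-level tracking of dominant gut microbes across shotgun
    metagenomic samples using a window-based single-nucleotide-variant
    similarity (WSS) score. Builds per-species consensus SNV profiles from
    reads or pileups, gates sample pairs on genome coverage and depth,
    scores pair similarity over fixed genomic windows, calibrates
    per-species relatedness cut-offs from labeled pairs, and classifies
    post-transplant recipient strains as donor-derived, pre-transplant
    recipient-derived, or unrelated to both. Includes a seeded synthetic
    data generator (reference genomes, diverged strains, reads with
    controlled coverage, depth and error, and donor-recipient transplant
    scenarios with known strain origin) so the whole pipeline is testable
    without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
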