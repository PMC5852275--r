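Package: ctyper
Title: CRISPR Leader-End Amplicon Genotyping and Diversity Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Ctyper", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for typing bacterial populations by the
    leader end of a CRISPR array from paired-end amplicon sequencing.
    Covers sliding-window quality trimming, read filtering, overlap-based
    pair merging, greedy identity clustering, direct-repeat detection and
    spacer extraction, mismatch-tolerant spacer dictionaries, CRISPR
    genotype (CT) assignment against a reference catalog including the
    definition of new genotypes, leader-end variant classification
    (origin / new+ / proto / others), protospacer search against foreign
    element references, and Shannon / Chao1 / rarefaction diversity
    statistics. A fully seeded synthetic-data module generates reference
    catalogs, seasonal compositions and paired-end FASTQ read sets with
    ground truth so every stage is testable without deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
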