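Package: bloodsift
Title: Decontamination and Microbial Signal Detection for Low-Biomass Blood Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether low-biomass blood (or other
    host-dominated) metagenomes contain genuine microbial signal. Implements
    species presence calling from Kraken2-style taxonomic profiles with joint
    read-count and relative-abundance thresholds, a four-stage batch-aware
    decontamination procedure (batch-prevalence, within-batch correlation of
    centred log-ratio abundances, multi-batch detection, and maximum read
    count filters), annotation-based enrichment randomization tests, SparCC
    compositional co-occurrence networks with cross-cohort edge intersection,
    coverage-based bacterial replication analysis (peak-to-trough ratio with
    origin/terminus localization and cumulative GC-skew cross-validation),
    and a per-cohort host-phenotype association screen with pooled
    Benjamini-Hochberg correction. A synthetic-data module generates
    batch-structured contaminated count matrices, phenotypes and circular
    genome coverage with planted truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
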