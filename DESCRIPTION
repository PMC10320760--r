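Package: cxxxscreen
Title: Saturation Screen Analysis of C-Terminal CXXX Motifs for Farnesylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for a yeast competitive-growth saturation screen
    of all 8,000 C-terminal CXXX motifs as farnesyltransferase substrates.
    Converts amplicon FASTQ reads into per-replicate motif counts, pools
    replicates per temperature condition and computes pseudocount-corrected
    enrichment factors (EF), builds the three position-pair heatmaps of mean
    EF with pattern detection, computes the summed contextual HM prenylation
    score, fits an interpretable entropy-based decision tree over residue-set
    features, benchmarks predictors against a packaged gel-shift reference
    table, and ships a full synthetic screen simulator (library imbalance,
    two-temperature selection, multinomial read sampling with Phred
    qualities) so every stage is testable without the original sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    Biostrings,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
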