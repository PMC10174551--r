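Package: contiguard
Title: Reference-Free Detection of Misassembled Metagenome Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects misassembled contigs in metagenome assemblies without
    reference genomes. Reads aligned back to their contigs are summarized into
    per-position pileup features (coverage, base composition, SNV counts,
    proper-pair and orphan counts, mapping-quality / alignment-score / insert-size
    statistics), which a deep residual convolutional network with masked global
    average pooling maps to a per-contig misassembly probability. Includes a
    desk-scale simulation pipeline that generates labeled chimeric contigs
    (relocations, inversions, translocations, interspecies translocations) with
    known breakpoints from lognormal mock communities, truth-based read
    alignment, CPU training with AUPRC-based model selection, chunked prediction
    for long contigs, precision-recall evaluation, score-based assembly
    filtering with N50 reporting, and misassembly-rate estimation for ranking
    assembler parameter settings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
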