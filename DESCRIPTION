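Package: kmersweep
Title: Reference-Free Decontamination of Ancient Oral Metagenomes by
    Trusted k-mer Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies metagenomic sequencing reads as ancient-oral or
    contaminant without reference genomes or sequenced controls. A trusted
    set of oral k-mers is derived from a labelled k-mer-by-sample presence
    matrix (keep k-mers seen in ancient or modern oral samples and in no
    skin or sediment/soil sample), stored in a Bloom filter, and reads are
    classified with a two-pass anchor algorithm: reads with two consecutive
    k-mer matches against the filter become anchors, all anchor k-mers form
    an exact set, and reads with at least a threshold proportion of their
    k-mers in that set are retained. Includes a synthetic-mixture simulator
    and a sensitivity/specificity evaluation harness with ROC threshold
    scanning, plus a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
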