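Package: mirtss
Title: Brain-Specific MicroRNA Transcription Start Site Prediction from
    Genetic and Epigenetic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts transcription start sites (TSSs) of microRNAs
    expressed in brain tissue from 1 kb genomic windows. Five families of
    features are extracted from soft-masked sequence and per-sample DNA
    methylation tracks: n-mer frequencies, reverse-complement palindrome
    frequencies, promoter-associated wildcard motifs, CpG-island
    observed/expected and G+C statistics, and coverage-weighted
    methylation scores normalised by CpG-island count. Features are
    ranked by the two-class F-score and selected greedily by a
    variable-weighted maximal-relevance minimal-redundancy criterion on
    normalised mutual information; a random-forest classifier is
    evaluated by repeated stratified cross-validation with accuracy,
    sensitivity, specificity, precision and the Matthews correlation
    coefficient. A synthetic-data generator emulates promoter-like
    positive windows, repeat-decoy negatives and beta-distributed
    methylomes so the full pipeline can be exercised without genome
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    GenomicRanges,
    randomForest,
    rtracklayer,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
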