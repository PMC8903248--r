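Package: packScan
Title: Discovery, Clustering and Classification of Pack-TYPE Transposable Elements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates Pack-TYPE and other terminal-inverted-repeat (TIR) DNA
    transposons in plant genomes from short TIR seed sequences. Candidate
    elements are detected by approximate (Levenshtein) semi-global matching of
    inward-facing TIR pairs, verified by target-site-duplication (TSD)
    similarity, grouped into families by greedy centroid clustering, and
    classified as autonomous, Pack-TYPE or non-Pack from similarity hits
    against transposase and coding-sequence references. Includes a
    reversed-TIR decoy benchmark with ROC/AUC summaries, family-level
    statistics (local hopping, TIR k-mer clustering, TSD composition) and a
    synthetic-genome simulator with planted ground truth for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Annotation, Genetics, SequenceMatching, Alignment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
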