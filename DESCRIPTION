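Package: denovotx
Title: De Novo Assembly and Differential Expression Analysis of Bacterial
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles bacterial transcriptomes de novo from RNA-seq reads
    using a two-stage algorithm that couples a memory-bounded de Bruijn graph
    with a Burrows-Wheeler (FM) index: candidate transcripts are extracted by
    greedy highest-frequency path traversal, then reads are aligned back
    full-length to retain well-supported transcript regions. Downstream
    analyses include upper-quartile normalization, RPKM-like transcript
    abundance, negative-binomial exact tests for differential expression with
    local-regression variance smoothing, and Benjamini-Hochberg FDR control.
    Includes a five-metric assembly evaluation framework (specificity,
    sensitivity, contiguity, reads-mapping-back-to-transcripts, accuracy)
    against an annotated genome, and a synthetic RNA-seq data generator for
    validation without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
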