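Package: egrin2
Title: Ensemble Post-Processing for Environment and Gene Regulatory
    Influence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes ensembles of biclustering runs over microbial
    transcriptome compendia into a second-generation gene regulatory network
    model. Clusters de novo cis-regulatory motifs into gene regulatory
    elements (GREs) with Markov clustering over a motif-similarity network,
    scans genomes with exact dynamic-programming match p-values, builds the
    gene-gene co-occurrence network, extracts its multiscale backbone with
    the disparity filter, detects conditionally co-regulated modules
    (corems) by link-community detection under the partition-density
    objective, characterises each corem's active conditions with a
    permutation test on the relative standard deviation of expression,
    matches GREs to transcription factors by binding-site overlap, and
    evaluates the derived regulatory network with precision-recall and
    fitness-coherence statistics. Includes a deterministic synthetic-fixture
    generator with planted motifs, modules and condition blocks so every
    stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
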