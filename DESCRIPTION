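Package: crossSCI
Title: Cross-Species Comparison of Spinal-Cord-Injury Transcriptional Responses
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for comparing the transcriptional response to
    spinal cord injury across vertebrates with different regenerative
    capacities. Provides a triple-criterion differential-expression filter
    (FDR, fold change, read floor), cross-species expression-behavior
    classification of orthologs (departing / coincident / ambiguous),
    phylogenetic presence/absence profiling with annotation-gap rescue and
    fish-outgroup resolution, ortholog nucleotide-identity distributions via
    global alignment, Fisher's exact term enrichment with information-content
    filtering, and confidence-filtered interaction-network clustering with
    behavior overlays. A synthetic-data module with planted ground truth
    emulates every input so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    jsonlite,
    mclust,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
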