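Package: repforge
Title: De Novo Assembly of Repeat Consensus Sequences from Raw Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs consensus sequences of high-copy, low-divergence
    genomic repeat families (transposable elements, satellites) directly from
    unassembled paired-end shotgun reads, without a reference genome. Frequent
    k-mers -- those whose count exceeds a multiple of the average k-mer
    frequency -- are selected, partitioned into overlapping frequency bins, and
    assembled into raw contigs with a unitig de Bruijn assembler; raw contigs
    are then merged into long repeats through a directed overlap graph
    (suffix-prefix alignment, read-pair support, strongly connected component
    condensation, topological ordering, greedy maximal-path traversal) and
    validated by re-mapping reads and filtering on per-base coverage. Includes
    assembly evaluation statistics (reference-library hits, greedy and
    longest-single coverage, N50) and a paired-end read simulator with planted
    repeat families for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
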