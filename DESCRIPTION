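Package: orfgraph
Title: Gene Finding in Assembly Graphs by Anchor-Path Extension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds complete protein-coding genes whose sequences are scattered
    over multiple edges of a (meta)genomic assembly graph. Alignment-derived
    anchor paths are extended to in-frame start and stop codons by a
    frameshift-tracked breadth-first search, candidate coding paths are
    enumerated by bounded exhaustive search, filtered against assembler
    contigs via unique-edge compatibility, classified against a database of
    known proteins, clustered by single linkage, and reduced to representative
    sequences covering all long cluster edges. Includes a deterministic
    synthetic-fixture generator that embeds known genes in bubble and tangle
    graph structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    readr,
    rlang,
    stringi,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
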