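Package: splitkit
Title: Alignment-Free Phylogenetic Splits from Shared k-mers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment- and reference-free phylogeny estimation from whole
    genomes, assemblies, gene predictions, protein sequences or raw reads.
    k-mers shared by a subset of input genomes are interpreted as weighted
    phylogenetic splits; split sets are filtered greedily to compatible
    (tree) or weakly compatible (network) subsets, annotated with bootstrap
    support via binomial resampling of k-mer content, and written as
    SplitsTree-compatible NEXUS, Newick, or plain TSV. Includes a per-genome
    minimum-abundance filter for sequencing-error k-mers in read data,
    automatic translation under selectable NCBI genetic codes for
    amino-acid mode, and a synthetic-data generator (sequences evolved
    along a known tree, reads with errors) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
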