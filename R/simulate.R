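#' Simulate genomes evolved along a known tree
#'
#' Draws a uniform random root DNA sequence and evolves it down a
#' generated tree: on every branch each site mutates independently with
#' probability `sub_prob`, replacing the base uniformly by one of the
#' three alternatives (a Jukes–Cantor-like model, sufficient to create
#' k-mer-distinguishable lineages; no indels or recombination). The true
#' tree and its split decomposition are returned as ground truth, so
#' end-to-end recovery is testable without external data.
#'
#' @param n_taxa Number of leaves, >= 3.
#' @param seq_length Root sequence length in bp.
#' @param sub_prob Per-site substitution probability per branch, in
#'   `[0, 1)`.
#' @param tree_shape `"random-binary"`, `"caterpillar"` or `"balanced"`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param dir Optional directory: when given, one FASTA per leaf is
#'   written (`<id>.fasta`, or `.fasta.gz` with `gzip = TRUE`).
#' @param gzip Compress written FASTA files.
#' @return A list with `sequences` (named character vector),
#'   `tree` (`phylo`, unit branch lengths), `true_splits` (`split_set`
#'   of the tree's non-trivial + trivial splits, unit weights),
#'   `taxa`, and `files` (paths, when `dir` given).
#' @export
simulate_genomes <- function(n_taxa = 8L, seq_length = 50000L,
                             sub_prob = 0.01,
                             tree_shape = c("random-binary", "caterpillar",
                                            "balanced"),
                             seed = 1L, dir = NULL, gzip = FALSE) {
  tree_shape <- match.arg(tree_shape)
  if (n_taxa < 3L) abort("n_taxa must be >= 3")
  if (sub_prob < 0 || sub_prob >= 1) abort("sub_prob must be in [0, 1)")
  with_local_seed(seed, function() {
    taxa <- sprintf("g%02d", seq_len(n_taxa))
    tree <- switch(tree_shape,
      "random-binary" = ape::rtree(n_taxa, tip.label = taxa),
      "caterpillar" = caterpillar_tree(taxa),
      "balanced" = balanced_tree(taxa))
    tree$edge.length <- rep(1, nrow(tree$edge))
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, seq_length, replace = TRUE)
    n_nodes <- max(tree$edge)
    seqs <- vector("list", n_nodes)
    root_node <- n_taxa + 1L
    seqs[[root_node]] <- root
    # edges of a phylo are parent-before-child in preorder after reorder()
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; chl <- tr$edge[e, 2L]
      seqs[[chl]] <- mutate_sites(seqs[[par]], sub_prob, bases)
    }
    leaf_seqs <- vapply(seq_len(n_taxa),
                        function(i) paste(seqs[[i]], collapse = ""),
                        character(1))
    names(leaf_seqs) <- tree$tip.label
    leaf_seqs <- leaf_seqs[taxa]
    true_splits <- tree_splits(tree, taxa = taxa)
    files <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files <- vapply(taxa, function(t) {
        f <- file.path(dir, paste0(t, if (gzip) ".fasta.gz" else ".fasta"))
        con <- if (gzip) gzfile(f, "wt") else file(f, "wt")
        writeLines(c(paste0(">", t), leaf_seqs[[t]]), con)
        close(con)
        f
      }, character(1))
    }
    list(sequences = leaf_seqs, tree = tree, true_splits = true_splits,
         taxa = taxa, files = files)
  })
}

mutate_sites <- function(seq, p, bases) {
  if (p <= 0) return(seq)
  hit <- which(stats::runif(length(seq)) < p)
  if (length(hit) == 0L) return(seq)
  cur <- seq[hit]
  # uniform choice among the three alternative bases
  alt <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1))
  seq[hit] <- alt
  seq
}

caterpillar_tree <- function(taxa) {
  n <- length(taxa)
  nw <- taxa[n]
  for (i in (n - 1L):1L) nw <- paste0("(", taxa[i], ",", nw, ")")
  ape::read.tree(text = paste0(nw, ";"))
}

balanced_tree <- function(taxa) {
  build <- function(t) {
    if (length(t) == 1L) return(t)
    h <- ceiling(length(t) / 2)
    paste0("(", build(t[seq_len(h)]), ",", build(t[-seq_len(h)]), ")")
  }
  ape::read.tree(text = paste0(build(taxa), ";"))
}

#' Simulate error-prone reads from a genome
#'
#' Samples reads of fixed length uniformly over start positions (both
#' strands) to a target mean coverage, then introduces i.i.d. substitution
#' errors at `error_rate` per base. Qualities are a constant dummy.
#' Error provenance is tracked: the returned tibble records each read's
#' position, strand and error offsets, so error-derived k-mers can be
#' identified exactly when validating the abundance filter.
#'
#' @param sequence A single genome sequence (character scalar).
#' @param coverage Target mean coverage, >= 1.
#' @param read_length Read length in bp (must not exceed the genome).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param path Optional FASTQ output path (`.gz` suffix compresses).
#' @return A tibble of class `sk_reads` with columns `read_id`, `start`,
#'   `strand`, `sequence`, `n_errors`; attributes `genome` (the input
#'   sequence) and `path` when written.
#' @export
simulate_reads <- function(sequence, coverage = 30, read_length = 100L,
                           error_rate = 0.02, seed = 1L, path = NULL) {
  L <- nchar(sequence)
  if (read_length > L) abort("read_length exceeds genome length")
  if (coverage < 1) abort("coverage must be >= 1")
  with_local_seed(seed, function() {
    n_reads <- ceiling(coverage * L / read_length)
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    raw <- substring(sequence, starts, starts + read_length - 1L)
    raw[strands == "-"] <- reverse_complement(raw[strands == "-"])
    reads <- character(n_reads)
    n_err <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      chars <- strsplit(raw[[i]], "")[[1L]]
      hit <- which(stats::runif(read_length) < error_rate)
      if (length(hit) > 0L) {
        chars[hit] <- vapply(chars[hit], function(b)
          sample(setdiff(bases, b), 1L), character(1))
      }
      reads[[i]] <- paste(chars, collapse = "")
      n_err[[i]] <- length(hit)
    }
    out <- tibble(read_id = sprintf("read%06d", seq_len(n_reads)),
                  start = starts, strand = strands, sequence = reads,
                  n_errors = n_err)
    if (!is.null(path)) {
      con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else
        file(path, "wt")
      qual <- strrep("I", read_length)
      writeLines(as.vector(rbind(paste0("@", out$read_id), out$sequence,
                                 "+", qual)), con)
      close(con)
    }
    structure(out, genome = sequence, path = path,
              class = c("sk_reads", class(tibble())))
  })
}

#' Classify read k-mers by provenance
#'
#' Splits the distinct canonical k-mers of a read set into *genomic*
#' (also present in the error-free source genome) and *error-derived*
#' (created by simulated sequencing errors).
#'
#' @param reads An `sk_reads` tibble from [simulate_reads()].
#' @param k k-mer length.
#' @return A list with character vectors `genomic` and `error_derived`,
#'   plus `genome_keys` (all distinct canonical k-mers of the source
#'   genome).
#' @export
kmer_provenance <- function(reads, k) {
  genome <- attr(reads, "genome")
  genome_keys <- unique(extract_kmers(genome, k, "dna"))
  read_keys <- unique(extract_kmers(reads$sequence, k, "dna"))
  list(genomic = intersect(read_keys, genome_keys),
       error_derived = setdiff(read_keys, genome_keys),
       genome_keys = genome_keys)
}
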