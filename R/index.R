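#' Build the partitioned k-mer occurrence index
#'
#' Scans every genome of an input table and builds the k-mer -> genome-set
#' occurrence table at the heart of the method. Two structures are
#' maintained, mirroring the singleton-promotion optimization: k-mers seen
#' in exactly one genome so far live in a *singleton map* (key -> genome
#' index); the first observation from a second genome promotes the key
#' into the occurrence table proper (key -> genome bit set). The key space
#' is partitioned into `m` sub-indices by [partition_of()]; each key
#' belongs to exactly one sub-index, which is the unit of mutual exclusion
#' under concurrent ingestion.
#'
#' Before a k-mer is registered for a genome it must pass that genome's
#' abundance filter: its within-genome multiplicity (canonical k-mers,
#' summed over all of the genome's files) must reach the genome's
#' `abundance_min`. Each passing key is registered exactly once per
#' genome.
#'
#' `workers` schedules genome scanning in worker-interleaved order, but
#' registration always merges in canonical genome order, so the resulting
#' index is identical for every worker count (including 1).
#'
#' @param specs An `sk_inputs` tibble from [parse_input_list()] /
#'   [input_table()], or a named list / named character vector of raw
#'   sequences (names = genome ids) for programmatic use.
#' @param k k-mer length. Default: 31 for DNA, 10 for protein.
#' @param m Number of partitions (default 4096, chosen to exceed any
#'   realistic worker count by orders of magnitude).
#' @param workers Number of ingestion workers (affects scheduling only;
#'   results are exact and identical for any value).
#' @param protein Logical; protein-alphabet mode.
#' @param code Optional codon map from [genetic_code()]: in protein mode,
#'   DNA-like records are translated under it first (see
#'   [translate_records()]).
#' @return An object of class `kmer_index`: a list with elements
#'   `k`, `m`, `alphabet`, `genome_ids`, `singleton` (named integer
#'   vector: key -> genome index) and `shared` (named character vector:
#'   key -> comma-joined ascending genome indices, i.e. the bit set).
#' @examples
#' idx <- kmer_index(c(gA = "ACGTACGTAC", gB = "ACGTACGTTT"), k = 5)
#' glance(idx)
#' @export
kmer_index <- function(specs, k = NULL, m = 4096L, workers = 1L,
                       protein = FALSE, code = NULL) {
  if (is.character(specs) || (is.list(specs) && !is.data.frame(specs))) {
    specs <- specs_from_sequences(specs, protein)
  }
  alphabet <- if (isTRUE(protein) || identical(specs$seq_kind[[1L]], "protein"))
    "protein" else "dna"
  k <- as.integer(k %||% if (alphabet == "dna") 31L else 10L)
  if (k < 1L) abort("k must be >= 1")
  if (m < 1L) abort("m must be >= 1")
  idx <- new_kmer_index(k, as.integer(m), alphabet, specs$genome_id)
  n <- nrow(specs)
  # worker-interleaved scan order; merge order stays canonical
  workers <- max(1L, as.integer(workers))
  scan_order <- unlist(lapply(seq_len(workers), function(w)
    if (w > n) integer(0) else seq.int(w, n, by = workers)),
    use.names = FALSE)
  keysets <- vector("list", n)
  for (g in scan_order) {
    keysets[[g]] <- genome_keyset(specs[g, ], k, alphabet, code)
  }
  for (g in seq_len(n)) {
    idx <- register_keys(idx, keysets[[g]], g)
  }
  idx
}

new_kmer_index <- function(k, m, alphabet, genome_ids) {
  structure(list(k = k, m = m, alphabet = alphabet,
                 genome_ids = as.character(genome_ids),
                 singleton = setNames(integer(0), character(0)),
                 shared = setNames(character(0), character(0))),
            class = "kmer_index")
}

specs_from_sequences <- function(seqs, protein) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("raw sequences must have unique names (genome ids)")
  }
  tibble(genome_id = names(seqs),
         paths = lapply(seqs, identity),
         abundance_min = 1L,
         seq_kind = if (isTRUE(protein)) "protein" else "dna",
         inline = TRUE)
}

# distinct canonical keys of one genome passing its abundance threshold,
# counted across all of the genome's files
genome_keyset <- function(spec, k, alphabet, code = NULL) {
  if ("inline" %in% names(spec) && isTRUE(spec$inline[[1L]])) {
    res <- unlist(spec$paths[[1L]], use.names = FALSE)
    res <- toupper(res)
    if (alphabet == "dna") res <- chartr("U", "T", res)
  } else {
    recs <- read_sequences(spec)
    res <- recs$residues
  }
  if (alphabet == "protein" && !is.null(code)) {
    dna <- is_dna_like(res)
    res[dna] <- translate_dna(res[dna], code)
  }
  kmers <- extract_kmers(res, k, alphabet)
  amin <- spec$abundance_min %||% 1L
  abundance_filter(kmers, amin[[1L]] %||% 1L)
}

#' Apply the within-genome abundance filter
#'
#' Counts the multiplicity of each canonical k-mer within one genome and
#' keeps those reaching `abundance_min` (the `--qualify` threshold):
#' k-mers occurring fewer than `n` times per genome — typically
#' sequencing-error artifacts in read data — are dropped before indexing.
#'
#' @param kmers Character vector of canonical k-mers with multiplicity
#'   (one genome's full scan).
#' @param abundance_min Integer >= 1.
#' @return Character vector of distinct keys passing the filter, in first-
#'   appearance order.
#' @export
abundance_filter <- function(kmers, abundance_min = 1L) {
  uk <- unique(kmers)
  if (abundance_min <= 1L) return(uk)
  counts <- tabulate(match(kmers, uk), nbins = length(uk))
  uk[counts >= abundance_min]
}

#' Register one genome's keys in the index
#'
#' Low-level ingestion step (called by [kmer_index()] in canonical genome
#' order): new keys enter the singleton map; keys already in the singleton
#' map under a different genome are promoted to the occurrence table with
#' both genomes' bits set; keys already in the occurrence table gain the
#' genome's bit.
#'
#' @param index A `kmer_index`.
#' @param keys Distinct canonical keys passing the genome's abundance
#'   filter (see [abundance_filter()]).
#' @param genome Genome index (1-based position in `index$genome_ids`).
#' @return The updated `kmer_index`.
#' @export
register_keys <- function(index, keys, genome) {
  g <- as.integer(genome)
  if (g < 1L || g > length(index$genome_ids)) abort("genome index out of range")
  if (length(keys) == 0L) {
    warn(paste0("genome '", index$genome_ids[g],
                "' contributed no k-mers (sequences shorter than k?)"))
    return(index)
  }
  in_shared <- match(keys, names(index$shared))
  hit_s <- !is.na(in_shared)
  if (any(hit_s)) {
    index$shared[in_shared[hit_s]] <-
      paste0(index$shared[in_shared[hit_s]], ",", g)
  }
  rest <- keys[!hit_s]
  in_single <- match(rest, names(index$singleton))
  hit_1 <- !is.na(in_single)
  if (any(hit_1)) {
    promoted <- setNames(
      paste0(index$singleton[in_single[hit_1]], ",", g),
      rest[hit_1])
    index$shared <- c(index$shared, promoted)
    index$singleton <- index$singleton[-in_single[hit_1]]
  }
  new <- rest[!hit_1]
  if (length(new) > 0L) {
    index$singleton <- c(index$singleton, setNames(rep.int(g, length(new)), new))
  }
  index
}

#' Dump the occurrence table
#'
#' @param index A `kmer_index`.
#' @return A tibble with one row per distinct indexed key: `kmer`,
#'   `partition` (via [partition_of()]), `genomes` (comma-separated genome
#'   ids) and `n_genomes`.
#' @export
index_dump <- function(index) {
  keys <- c(names(index$singleton), names(index$shared))
  pats <- c(as.character(index$singleton), unname(index$shared))
  ids <- vapply(strsplit(pats, ",", fixed = TRUE), function(p)
    paste(index$genome_ids[as.integer(p)], collapse = ","), character(1))
  out <- tibble(kmer = keys,
                partition = partition_of(keys, index$m, index$alphabet),
                genomes = ids,
                n_genomes = lengths(strsplit(pats, ",", fixed = TRUE)))
  dplyr::arrange(out, .data$kmer)
}

#' View one sub-index
#'
#' @param index A `kmer_index`.
#' @param p Partition number in `[0, m)`.
#' @return A tibble of the keys in partition `p` (columns as
#'   [index_dump()]).
#' @export
sub_index <- function(index, p) {
  d <- index_dump(index)
  d[d$partition == p, ]
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, " (", x$alphabet, "), m=", x$m,
      " partitions\n", sep = "")
  cat("  genomes:       ", length(x$genome_ids), "\n", sep = "")
  cat("  distinct keys: ", length(x$singleton) + length(x$shared),
      " (", length(x$singleton), " singleton, ", length(x$shared),
      " shared)\n", sep = "")
  invisible(x)
}

#' @export
glance.kmer_index <- function(x, ...) {
  tibble(k = x$k, m = x$m, alphabet = x$alphabet,
         n_genomes = length(x$genome_ids),
         n_kmers = length(x$singleton) + length(x$shared),
         n_singleton = length(x$singleton),
         n_shared = length(x$shared))
}
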