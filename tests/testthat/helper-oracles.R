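# Independent reference implementations used to validate the package's
# own code paths. These deliberately take different routes: per-k-mer
# reverse complementation, table()-based counting, split()/tapply-based
# pattern histograms, exhaustive quartet enumeration.

# per-k-mer canonicalization via Biostrings (independent of the
# full-sequence-rc shortcut used by extract_kmers)
oracle_canonical <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

# forward k-mer windows of one sequence, broken at non-ACGT characters
oracle_windows <- function(seq, k) {
  seq <- toupper(seq)
  out <- character(0)
  for (seg in strsplit(seq, "[^ACGT]+")[[1L]]) {
    L <- nchar(seg)
    if (L >= k) out <- c(out, substring(seg, 1:(L - k + 1L), k:L))
  }
  out
}

# naive single-threaded dictionary oracle for the occurrence table:
# genomes is a named list (genome id -> character vector of sequences);
# amin is a scalar or per-genome vector. Returns a named list
# key -> sorted integer vector of genome indices.
oracle_index <- function(genomes, k, amin = 1L) {
  amin <- rep_len(amin, length(genomes))
  entries <- list()
  for (g in seq_along(genomes)) {
    km <- unlist(lapply(genomes[[g]], oracle_windows, k = k))
    if (length(km) == 0L) next
    km <- oracle_canonical(km)
    cnt <- table(km)
    keys <- names(cnt)[cnt >= amin[[g]]]
    entries[[g]] <- keys
  }
  long_g <- rep(seq_along(entries), lengths(entries))
  long_k <- unlist(entries)
  if (length(long_k) == 0L) return(list())
  lapply(split(long_g, long_k), function(v) sort(unique(v)))
}

# occurrence map of a built kmer_index in the oracle's shape
index_as_map <- function(idx) {
  keys <- c(names(idx$singleton), names(idx$shared))
  if (length(keys) == 0L) return(list())
  pats <- c(as.character(idx$singleton), unname(idx$shared))
  m <- lapply(strsplit(pats, ",", fixed = TRUE), as.integer)
  names(m) <- keys
  m[order(names(m))]
}

# split weights as a named vector (side_key -> weight)
weights_by_side <- function(ss) {
  setNames(ss$weight, ss$side_key)
}

# oracle split histogram from an oracle index map
oracle_split_weights <- function(map, n_genomes) {
  pats <- vapply(map, paste, character(1), collapse = ",")
  cnt <- table(pats)
  out <- numeric(0)
  for (p in names(cnt)) {
    side <- as.integer(strsplit(p, ",", fixed = TRUE)[[1L]])
    if (length(side) == n_genomes) next
    if (1L %in% side) side <- setdiff(seq_len(n_genomes), side)
    key <- paste(sort(side), collapse = ",")
    out[key] <- (out[key] %||% 0) + as.numeric(cnt[[p]])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

# brute-force pairwise compatibility via explicit set intersections
oracle_compatible <- function(s1, s2, n) {
  a1 <- s1; b1 <- setdiff(seq_len(n), s1)
  a2 <- s2; b2 <- setdiff(seq_len(n), s2)
  length(intersect(a1, a2)) == 0 || length(intersect(a1, b2)) == 0 ||
    length(intersect(b1, a2)) == 0 || length(intersect(b1, b2)) == 0
}

# quartet-enumeration oracle for weak compatibility: forbidden iff four
# distinct taxa x0..x3 exist with split i separating {x0, xi} from the
# other two
oracle_weakly <- function(s1, s2, s3, n) {
  mem <- lapply(list(s1, s2, s3), function(s) {
    m <- logical(n); m[s] <- TRUE; m
  })
  seps <- function(m, a, b, c, d) {
    (m[a] && m[b] && !m[c] && !m[d]) || (!m[a] && !m[b] && m[c] && m[d])
  }
  for (x0 in 1:n) for (x1 in 1:n) for (x2 in 1:n) for (x3 in 1:n) {
    if (anyDuplicated(c(x0, x1, x2, x3))) next
    if (seps(mem[[1L]], x0, x1, x2, x3) &&
        seps(mem[[2L]], x0, x2, x1, x3) &&
        seps(mem[[3L]], x0, x3, x1, x2)) return(FALSE)
  }
  TRUE
}

# straightforward re-implementation of the greedy filter for
# cross-checking (same ordering contract, independent loop structure)
oracle_greedy <- function(ss, mode, n) {
  lex <- vapply(ss$side, function(s) paste(sprintf("%09d", s), collapse = ","),
                character(1))
  ord <- order(-ss$weight, lengths(ss$side), lex)
  kept <- list()
  kept_keys <- character(0)
  for (i in ord) {
    side <- ss$side[[i]]
    if (length(side) %in% c(1L, n - 1L)) {
      kept_keys <- c(kept_keys, ss$side_key[[i]])
      next
    }
    ok <- TRUE
    if (mode %in% c("strict", "tree")) {
      for (ks in kept) if (!oracle_compatible(side, ks, n)) { ok <- FALSE; break }
    } else {
      nk <- length(kept)
      if (nk >= 2L) {
        for (a in seq_len(nk - 1L)) {
          for (b in (a + 1L):nk) {
            if (!oracle_weakly(side, kept[[a]], kept[[b]], n)) ok <- FALSE
          }
          if (!ok) break
        }
      }
    }
    if (ok) {
      kept[[length(kept) + 1L]] <- side
      kept_keys <- c(kept_keys, ss$side_key[[i]])
    }
  }
  sort(kept_keys)
}

# random weighted split set over n taxa (proper non-empty subsets)
random_split_set <- function(n, n_splits, include_trivial = TRUE) {
  sides <- list()
  while (length(sides) < n_splits) {
    sz <- sample(1:(n - 1L), 1L)
    sides[[length(sides) + 1L]] <- sort(sample(n, sz))
  }
  if (include_trivial) sides <- c(sides, as.list(seq_len(n)))
  w <- sample(1:50, length(sides), replace = TRUE)
  split_set(sides, w, taxa = sprintf("t%d", seq_len(n)))
}

# write a named vector of sequences as one FASTA per genome, return an
# sk_inputs table
fasta_inputs <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame()),
                         gzip = FALSE, abundance_min = 1L) {
  files <- vapply(names(seqs), function(id) {
    f <- file.path(dir, paste0(id, if (gzip) ".fasta.gz" else ".fasta"))
    con <- if (gzip) gzfile(f, "wt") else file(f, "wt")
    writeLines(c(paste0(">", id), seqs[[id]]), con)
    close(con)
    f
  }, character(1))
  input_table(as.list(files), genome_id = names(seqs),
              abundance_min = abundance_min)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
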