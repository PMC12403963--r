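# k-mer alphabets. DNA uses 2-bit codes, protein 5-bit codes, for the
# partition function (key read as an unsigned integer modulo m).
sk_alphabet <- function(alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "dna") {
    list(name = "dna", letters = c("A", "C", "G", "T"), bits = 2L, base = 4L)
  } else {
    list(name = "protein",
         letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
         bits = 5L, base = 32L)
  }
}

# split a sequence into maximal runs of valid alphabet characters; any
# other character (N, ambiguity codes, stop '*', ...) breaks the window
valid_segments <- function(residues, alphabet = "dna") {
  ab <- sk_alphabet(alphabet)
  pat <- paste0("[^", paste(ab$letters, collapse = ""), "]+")
  segs <- unlist(strsplit(residues, pat), use.names = FALSE)
  segs[nzchar(segs)]
}

#' Extract canonical k-mers from sequences
#'
#' Slides a window of length `k` over each sequence. Characters outside
#' the active alphabet (DNA: `ACGT`; protein: the 20 amino-acid letters)
#' terminate the current window; scanning resumes after them. In DNA mode
#' each k-mer is canonicalized to the lexicographic minimum of itself and
#' its reverse complement, so both strands index identically; in protein
#' mode the k-mer itself is the key.
#'
#' @param residues Character vector of (uppercase) sequences.
#' @param k Window length, integer >= 1.
#' @param alphabet `"dna"` or `"protein"`.
#' @return Character vector of canonical k-mers in scan order (with
#'   multiplicity; not deduplicated).
#' @examples
#' extract_kmers("ACGTN" , k = 2)  # windows broken at N
#' extract_kmers("TTTT", k = 4)    # canonical form "AAAA"
#' @export
extract_kmers <- function(residues, k, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (k < 1L) abort("k must be >= 1")
  segs <- valid_segments(residues, alphabet)
  segs <- segs[nchar(segs) >= k]
  if (length(segs) == 0L) return(character(0))
  kmers <- unlist(lapply(segs, function(s) {
    L <- nchar(s)
    fwd <- substring(s, 1L:(L - k + 1L), k:L)
    if (alphabet == "dna") {
      rc_full <- reverse_complement(s)
      rc <- rev(substring(rc_full, 1L:(L - k + 1L), k:L))
      ifelse(fwd <= rc, fwd, rc)
    } else {
      fwd
    }
  }), use.names = FALSE)
  kmers
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences over `ACGT`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonicalize k-mers
#'
#' DNA: lexicographic minimum of the k-mer and its reverse complement;
#' protein: identity. All k-mers must have equal length and contain no
#' window-breaking characters (use [extract_kmers()] for raw sequences).
#'
#' @param kmers Character vector of k-mers.
#' @inheritParams extract_kmers
#' @return Character vector of canonical keys.
#' @export
canonicalize <- function(kmers, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (length(kmers) == 0L) return(character(0))
  ab <- sk_alphabet(alphabet)
  bad <- grepl(paste0("[^", paste(ab$letters, collapse = ""), "]"), kmers)
  if (any(bad)) {
    abort(paste0("k-mer contains window-breaking character: ",
                 kmers[bad][1L]))
  }
  if (alphabet == "protein") return(kmers)
  rc <- reverse_complement(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Partition index of k-mer keys
#'
#' Maps each key to a partition in `[0, m)`: residues are encoded to
#' fixed-width bit codes (DNA: A=00, C=01, G=10, T=11; protein: 5-bit
#' codes in alphabetical order), the code string is read as an unsigned
#' integer, and the partition is that integer modulo `m`. Computed by
#' Horner's rule modulo `m`, which equals the direct big-integer
#' interpretation.
#'
#' @param keys Character vector of k-mer keys (equal length, valid
#'   alphabet).
#' @param m Number of partitions, integer >= 1.
#' @inheritParams extract_kmers
#' @return Integer vector of partition indices in `[0, m)`.
#' @examples
#' partition_of(c("AA", "AC"), m = 3)  # 0 and 1
#' @export
partition_of <- function(keys, m, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (m < 1L) abort("m must be >= 1")
  if (length(keys) == 0L) return(integer(0))
  ab <- sk_alphabet(alphabet)
  codes <- setNames(seq_along(ab$letters) - 1L, ab$letters)
  k <- nchar(keys[[1L]])
  val <- rep(0, length(keys))
  for (j in seq_len(k)) {
    cj <- codes[substr(keys, j, j)]
    if (anyNA(cj)) abort("invalid character in k-mer key")
    val <- (val * ab$base + cj) %% m
  }
  as.integer(unname(val))
}

#' Rolling partition values along a sequence
#'
#' Streaming variant of [partition_of()]: the partition of the window
#' starting at position `i+1` is derived from the window at `i` in
#' constant time (subtract the outgoing residue's contribution, shift,
#' add the incoming residue, all modulo `m`). Operates on the forward
#' windows of a single valid segment and agrees with [partition_of()]
#' at every position.
#'
#' @param segment A single sequence with no window-breaking characters.
#' @inheritParams partition_of
#' @param k Window length.
#' @return Integer vector of length `nchar(segment) - k + 1`.
#' @export
rolling_partitions <- function(segment, k, m, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  ab <- sk_alphabet(alphabet)
  codes <- setNames(seq_along(ab$letters) - 1L, ab$letters)
  L <- nchar(segment)
  if (L < k) return(integer(0))
  chars <- strsplit(segment, "")[[1L]]
  cs <- codes[chars]
  if (anyNA(cs)) abort("window-breaking character in segment")
  # 4^(k-1) mod m (resp. 32^(k-1)) by repeated modular multiplication
  pow <- 1
  for (i in seq_len(k - 1L)) pow <- (pow * ab$base) %% m
  out <- integer(L - k + 1L)
  v <- 0
  for (j in 1:k) v <- (v * ab$base + cs[j]) %% m
  out[1L] <- v
  if (L > k) {
    for (i in 2:(L - k + 1L)) {
      v <- ((v - cs[i - 1L] * pow) %% m + m) %% m
      v <- (v * ab$base + cs[i + k - 1L]) %% m
      out[i] <- v
    }
  }
  as.integer(out)
}
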