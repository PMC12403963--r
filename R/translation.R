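#' Look up an NCBI genetic code table
#'
#' Returns the codon map for an NCBI translation-table number. Table 1 is
#' the standard code. The tables themselves are taken from Biostrings;
#' available ids are 1-6, 9-16 and 21-26.
#'
#' @param code_id Integer NCBI translation table number.
#' @return A named character vector of length 64 mapping codons to
#'   amino-acid letters, with `"*"` marking stop codons, carrying the id as
#'   attribute `code_id`.
#' @examples
#' genetic_code(1)[c("ATG", "TAA")]
#' @export
genetic_code <- function(code_id = 1L) {
  id <- as.character(as.integer(code_id))
  map <- tryCatch(Biostrings::getGeneticCode(id),
                  error = function(e) {
                    abort(paste0("unknown genetic code table: ", code_id,
                                 " (available: ",
                                 paste(available_genetic_codes(), collapse = ", "),
                                 ")"))
                  })
  map <- chartr("U", "T", setNames(unname(map), chartr("U", "T", names(map))))
  stopifnot(length(map) == 64L, any(map == "*"))
  attr(map, "code_id") <- as.integer(code_id)
  map
}

#' @rdname genetic_code
#' @export
available_genetic_codes <- function() {
  as.integer(Biostrings::GENETIC_CODE_TABLE$id)
}

#' Translate DNA to amino acids (frame 1)
#'
#' Translates each sequence codon by codon in reading frame 1. Trailing
#' 1-2 nucleotides are dropped. Codons containing any character outside
#' `A/C/G/T` translate to `X`; stop codons are emitted as `*`, which is
#' outside the amino-acid k-mer alphabet and therefore breaks k-mer
#' windows downstream (no k-mer spans a stop).
#'
#' @param residues Character vector of DNA sequences (uppercase; `U`
#'   tolerated and read as `T`).
#' @param code A codon map from [genetic_code()] (default: standard code).
#' @return Character vector of amino-acid sequences; empty input gives
#'   empty output.
#' @examples
#' translate_dna("ATGAAA")       # "MK"
#' translate_dna("ATGTAAATG")    # "M*M" — the stop breaks k-mer windows
#' @export
translate_dna <- function(residues, code = genetic_code(1L)) {
  vapply(residues, function(s) {
    s <- chartr("U", "T", toupper(s))
    L <- nchar(s)
    nc <- L %/% 3L
    if (nc == 0L) return("")
    starts <- seq.int(1L, by = 3L, length.out = nc)
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify a sequence as DNA or protein
#'
#' A record is considered DNA iff at least `threshold` of its characters
#' are in `{A,C,G,T,N,U}` (protein sequences contain other letters almost
#' surely). Used in amino-acid mode to support mixed translated /
#' untranslated input.
#'
#' @param residues Character vector of sequences.
#' @param threshold Minimum DNA-alphabet fraction (default 0.95).
#' @return Logical vector.
#' @export
is_dna_like <- function(residues, threshold = 0.95) {
  vapply(residues, function(s) {
    L <- nchar(s)
    if (L == 0L) return(FALSE)
    n_dna <- L - nchar(gsub("[ACGTNU]", "", toupper(s)))
    n_dna / L >= threshold
  }, logical(1), USE.NAMES = FALSE)
}

#' Translate DNA records, pass protein records through
#'
#' Amino-acid mode ingestion rule: records whose residues look like DNA
#' (see [is_dna_like()]) are translated in frame 1 under `code`; all other
#' records are passed through unchanged as amino-acid sequences.
#'
#' @param records A tibble with a `residues` column (e.g. from
#'   [read_sequences()]).
#' @inheritParams translate_dna
#' @param threshold DNA-classification threshold, see [is_dna_like()].
#' @return The tibble with `residues` replaced by amino-acid sequences and
#'   a logical column `translated`.
#' @export
translate_records <- function(records, code = genetic_code(1L),
                              threshold = 0.95) {
  dna <- is_dna_like(records$residues, threshold)
  out <- records
  out$residues[dna] <- translate_dna(records$residues[dna], code)
  out$translated <- dna
  out
}
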