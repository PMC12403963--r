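#' Parse a list-of-inputs file into an input table
#'
#' Reads the file naming one genome per line and returns a tibble with one
#' row per genome, in file order (the order defines genome indices
#' throughout a run). Two dialects are auto-detected per line:
#'
#' * **plain**: the line is a single sequence file path; the genome id is
#'   the file basename stripped of a trailing `.gz` and one sequence-format
#'   extension (`.fasta`, `.fa`, `.fna`, `.ffn`, `.faa`, `.fastq`, `.fq`).
#' * **file-of-files** (the kmtricks dialect):
#'   `<id> : <path> [; <path>]* [! <min_abundance>]` — one genome may span
#'   several files (e.g. paired read files), and an optional trailing
#'   `! n` overrides the global minimum-abundance threshold for that genome
#'   only, so reads (filtered) and assemblies (unfiltered) can be mixed in
#'   one analysis.
#'
#' Blank lines and lines starting with `#` are skipped. Paths containing
#' `;` or `!` are not supported in the file-of-files dialect.
#'
#' @param path Path to the list file.
#' @param abundance_min Global minimum within-genome k-mer multiplicity
#'   (the `--qualify` threshold); integer >= 1. Per-genome `! n`
#'   annotations override it.
#' @param protein Logical; if `TRUE` the sequences are treated as
#'   amino-acid input (`seq_kind = "protein"`).
#' @return A tibble of class `sk_inputs` with columns `genome_id`
#'   (character, unique), `paths` (list of character vectors),
#'   `abundance_min` (integer) and `seq_kind` (`"dna"` or `"protein"`).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' f <- file.path(dir, "gA.fasta")
#' writeLines(c(">s1", "ACGTACGT"), f)
#' lst <- file.path(dir, "list.txt")
#' writeLines(f, lst)
#' parse_input_list(lst)
#' @export
parse_input_list <- function(path, abundance_min = 1L, protein = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("input list not found: ", path))
  }
  if (!is.numeric(abundance_min) || length(abundance_min) != 1L ||
      abundance_min < 1) {
    abort("`abundance_min` must be a single integer >= 1")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    abort(paste0("no inputs: ", path, " contains no input lines"))
  }
  base_dir <- dirname(path)
  rows <- lapply(keep, function(i) {
    parse_input_line(lines[[i]], i, as.integer(abundance_min), base_dir)
  })
  specs <- dplyr::bind_rows(rows)
  dup <- specs$genome_id[duplicated(specs$genome_id)]
  if (length(dup) > 0L) {
    bad <- specs$line[match(dup[1L], specs$genome_id, nomatch = 0L)]
    abort(paste0("duplicate genome id '", dup[1L], "' (line ",
                 specs$line[specs$genome_id == dup[1L]][2L], ")"))
  }
  missing <- unlist(specs$paths)[!file.exists(unlist(specs$paths))]
  if (length(missing) > 0L) {
    abort(paste0("input file not readable: ", missing[1L]))
  }
  specs$seq_kind <- if (isTRUE(protein)) "protein" else "dna"
  specs$line <- NULL
  class(specs) <- c("sk_inputs", class(specs))
  specs
}

# one line of the list file -> one-row tibble (resolves relative paths
# against the list file's directory)
parse_input_line <- function(line, lineno, global_min, base_dir) {
  txt <- trimws(line)
  if (grepl(":", txt, fixed = TRUE)) {
    # file-of-files dialect
    halves <- strsplit(txt, ":", fixed = TRUE)[[1L]]
    if (length(halves) != 2L) {
      abort(paste0("line ", lineno, ": expected '<id> : <paths>', got: ", txt))
    }
    id <- trimws(halves[1L])
    rest <- halves[2L]
    min_a <- global_min
    if (grepl("!", rest, fixed = TRUE)) {
      parts <- strsplit(rest, "!", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) {
        abort(paste0("line ", lineno, ": more than one '!' threshold"))
      }
      rest <- parts[1L]
      min_a <- suppressWarnings(as.integer(trimws(parts[2L])))
      if (is.na(min_a)) {
        abort(paste0("line ", lineno, ": abundance threshold is not an integer"))
      }
      if (min_a < 1L) {
        abort(paste0("line ", lineno, ": abundance threshold must be >= 1"))
      }
    }
    paths <- trimws(strsplit(rest, ";", fixed = TRUE)[[1L]])
    if (any(paths == "")) {
      abort(paste0("line ", lineno, ": empty path"))
    }
  } else {
    if (txt == "" || grepl("!", txt, fixed = TRUE) ||
        grepl(";", txt, fixed = TRUE)) {
      abort(paste0("line ", lineno, ": ambiguous plain path (contains ';' or '!')"))
    }
    paths <- txt
    id <- genome_id_from_path(txt)
    min_a <- global_min
  }
  if (id == "") abort(paste0("line ", lineno, ": empty genome id"))
  paths <- ifelse(grepl("^(/|~)", paths), paths, file.path(base_dir, paths))
  tibble(genome_id = id, paths = list(paths),
         abundance_min = as.integer(min_a), line = lineno)
}

genome_id_from_path <- function(path) {
  b <- basename(path)
  b <- sub("\\.gz$", "", b, ignore.case = TRUE)
  sub("\\.(fasta|fa|fna|ffn|faa|fastq|fq)$", "", b, ignore.case = TRUE)
}

#' Build an input table directly from files
#'
#' Programmatic alternative to [parse_input_list()]: one genome per element
#' of `paths`.
#'
#' @param paths Character vector of file paths, or a named list of character
#'   vectors (several files per genome; names become genome ids).
#' @param genome_id Optional character vector of ids (defaults to basenames).
#' @param abundance_min Integer scalar or vector of per-genome thresholds.
#' @inheritParams parse_input_list
#' @return An `sk_inputs` tibble (see [parse_input_list()]).
#' @export
input_table <- function(paths, genome_id = NULL, abundance_min = 1L,
                        protein = FALSE) {
  if (!is.list(paths)) paths <- as.list(paths)
  n <- length(paths)
  if (n == 0L) abort("no inputs")
  ids <- genome_id %||% names(paths) %||%
    vapply(paths, function(p) genome_id_from_path(p[[1L]]), character(1))
  if (is.null(names(paths)) && is.null(genome_id)) {
    ids <- vapply(paths, function(p) genome_id_from_path(p[[1L]]), character(1))
  }
  if (anyDuplicated(ids)) abort("duplicate genome ids")
  if (any(abundance_min < 1)) abort("abundance_min must be >= 1")
  specs <- tibble(genome_id = as.character(ids),
                  paths = lapply(paths, as.character),
                  abundance_min = as.integer(rep_len(abundance_min, n)),
                  seq_kind = if (isTRUE(protein)) "protein" else "dna")
  class(specs) <- c("sk_inputs", class(specs))
  specs
}

#' Write an input table back to the file-of-files format
#'
#' Round-trip companion of [parse_input_list()]: the written file re-parses
#' to an identical input table.
#'
#' @param specs An `sk_inputs` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_input_list <- function(specs, path) {
  lines <- vapply(seq_len(nrow(specs)), function(i) {
    paste0(specs$genome_id[[i]], " : ",
           paste(specs$paths[[i]], collapse = " ; "),
           " ! ", specs$abundance_min[[i]])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequence records for one genome
#'
#' Reads every record from every file of one input-table row. FASTA vs
#' FASTQ is auto-detected per file from the first record character, gzip
#' transparently (by content, not extension). FASTQ qualities are read and
#' discarded. Residues are uppercased; in DNA mode `U` is mapped to `T`.
#'
#' @param spec A one-row slice of an `sk_inputs` tibble (or the tibble and
#'   `genome` naming the row).
#' @param genome Optional genome id selecting a row when `spec` has several.
#' @return A tibble with columns `genome_id`, `header`, `residues`.
#' @export
read_sequences <- function(spec, genome = NULL) {
  if (nrow(spec) > 1L) {
    if (is.null(genome)) abort("`spec` has several rows; give `genome`")
    spec <- spec[spec$genome_id == genome, ]
    if (nrow(spec) != 1L) abort(paste0("unknown genome id: ", genome))
  }
  recs <- lapply(spec$paths[[1L]], read_sequence_file,
                 dna = identical(spec$seq_kind, "dna"))
  out <- dplyr::bind_rows(recs)
  out$genome_id <- spec$genome_id[[1L]]
  out[, c("genome_id", "header", "residues")]
}

# single file -> tibble(header, residues); Biostrings handles gzip and both
# formats; errors are re-signalled with the offending file named
read_sequence_file <- function(path, dna = TRUE) {
  if (!file.exists(path)) abort(paste0("sequence file not found: ", path))
  con <- gzfile(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0L) {
    abort(paste0("empty sequence file: ", path))
  }
  fmt <- if (startsWith(first, "@")) "fastq" else if (startsWith(first, ">"))
    "fasta" else abort(paste0("malformed record in ", path,
                              " near line 1: neither FASTA nor FASTQ"))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) {
      abort(paste0("malformed ", toupper(fmt), " in ", path, ": ",
                   conditionMessage(e)))
    })
  res <- toupper(as.character(set))
  if (dna) res <- chartr("U", "T", res)
  tibble(header = names(set) %||% as.character(seq_along(set)),
         residues = unname(res))
}
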