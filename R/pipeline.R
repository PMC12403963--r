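#' Run the full splits pipeline
#'
#' Single entry point wiring every stage: parse inputs -> (translate) ->
#' build k-mer index -> derive splits -> filter -> (bootstrap /
#' consensus) -> write outputs. Mirrors the command-line surface
#' (`--filter`, `--qualify`, `--code`, `--bootstrap`, `--label`,
#' `--threads`).
#'
#' @param inputs Path to a list-of-inputs file (plain or file-of-files
#'   dialect), or an `sk_inputs` tibble, or a named character vector of
#'   raw sequences.
#' @param k k-mer length (default 31 for DNA, 10 for protein).
#' @param filter `"none"`, `"strict"`, `"weakly"` or `"tree"` (`"tree"`
#'   is an alias of `"strict"`).
#' @param qualify Global minimum within-genome k-mer multiplicity
#'   (per-genome `! n` annotations in the file-of-files override it).
#' @param code NCBI genetic code id enabling amino-acid mode with
#'   automatic translation (`TRUE` is shorthand for table 1; `NULL` =
#'   DNA mode).
#' @param protein Treat input as amino-acid sequences without
#'   translation (implied by `code`).
#' @param bootstrap Number of bootstrap replicates (`NULL` = none).
#' @param seed Seed for bootstrap resampling.
#' @param consensus Optional support threshold in `[0, 1]`; keeps only
#'   splits at or above it (requires `bootstrap`).
#' @param support_flag Threshold below which splits are flagged as
#'   low-confidence in the report (default 0.75).
#' @param bootstrap_method See [resample_weights()].
#' @param threads Ingestion worker count (results are identical for any
#'   value).
#' @param m Number of index partitions.
#' @param nexus,newick,tsv Optional output paths. `newick` requires a
#'   tree-compatible filter.
#' @param label,colors Optional label / color TSV paths (see
#'   [parse_label_files()]).
#' @return A list of class `sk_run` with elements `splits` (filtered
#'   `split_set`, support-annotated when bootstrapped), `raw_splits`
#'   (pre-filter), `index`, `support` (`bootstrap_result` or `NULL`),
#'   and `report` (named list of run statistics).
#' @examples
#' sim <- simulate_genomes(n_taxa = 5, seq_length = 2000, seed = 7)
#' run <- sans_run(sim$sequences, k = 15, filter = "strict")
#' glance(run$splits)
#' @export
sans_run <- function(inputs, k = NULL,
                     filter = c("none", "strict", "weakly", "tree"),
                     qualify = 1L, code = NULL, protein = FALSE,
                     bootstrap = NULL, seed = 1L, consensus = NULL,
                     support_flag = 0.75,
                     bootstrap_method = c("per_kmer", "per_split"),
                     threads = 1L, m = 4096L,
                     nexus = NULL, newick = NULL, tsv = NULL,
                     label = NULL, colors = NULL) {
  filter <- match.arg(filter)
  bootstrap_method <- match.arg(bootstrap_method)
  t0 <- Sys.time()
  if (!is.null(consensus) && is.null(bootstrap)) {
    abort("`consensus` requires `bootstrap`")
  }
  if (isTRUE(code)) code <- 1L
  protein <- isTRUE(protein) || !is.null(code)
  code_map <- if (!is.null(code)) genetic_code(code) else NULL
  if (!is.null(newick) && !filter %in% c("strict", "tree")) {
    abort("`newick` output requires filter = 'strict' or 'tree'")
  }
  specs <- if (is.character(inputs) && length(inputs) == 1L &&
               file.exists(inputs) && is.null(names(inputs))) {
    parse_input_list(inputs, abundance_min = qualify, protein = protein)
  } else if (inherits(inputs, "sk_inputs")) {
    inputs
  } else {
    specs_from_sequences(inputs, protein)
  }
  idx <- kmer_index(specs, k = k, m = m, workers = threads,
                    protein = protein, code = code_map)
  raw <- derive_splits(idx)
  filtered <- if (filter == "none") raw else greedy_filter(raw, filter)
  support <- NULL
  if (!is.null(bootstrap)) {
    bmode <- if (filter == "none") "weakly" else filter
    support <- bootstrap_support(raw, replicates = bootstrap, seed = seed,
                                 filter_mode = bmode,
                                 method = bootstrap_method)
    if (!is.null(consensus)) {
      filtered <- consensus_splits(filtered, support, consensus)
    }
    filtered <- annotate_support(filtered, support)
  }
  labmap <- if (!is.null(label)) {
    parse_label_files(label, colors, taxa = sk_taxa(filtered))
  } else NULL
  if (!is.null(tsv)) write_splits_tsv(filtered, tsv)
  if (!is.null(nexus)) {
    write_split_nexus(filtered, nexus, support = support, labels = labmap)
  }
  if (!is.null(newick)) write_newick(filtered, newick, support = support)
  report <- list(
    version = as.character(utils::packageVersion("splitkit")),
    taxa = length(sk_taxa(filtered)),
    k = idx$k, m = idx$m, alphabet = idx$alphabet,
    qualify = unname(qualify),
    filter = filter,
    distinct_kmers = sk_total_kmers(raw),
    splits_before_filter = nrow(raw),
    splits_after_filter = nrow(filtered),
    bootstrap = bootstrap %||% 0L,
    seed = seed,
    flagged_low_support = if (is.null(support)) NA_integer_ else
      sum(flag_low_support(support, support_flag)$flagged[
        support$side_key %in% filtered$side_key]),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(list(splits = filtered, raw_splits = raw, index = idx,
                 support = support, labels = labmap, report = report),
            class = "sk_run")
}

#' @export
print.sk_run <- function(x, ...) {
  r <- x$report
  cat("<sk_run> ", r$taxa, " taxa | k=", r$k, " (", r$alphabet,
      ") | qualify=", r$qualify, " | filter=", r$filter, "\n",
      "  distinct k-mers: ", format(r$distinct_kmers),
      " | splits: ", r$splits_before_filter, " -> ",
      r$splits_after_filter, "\n", sep = "")
  if (r$bootstrap > 0) {
    cat("  bootstrap: ", r$bootstrap, " replicates (seed ", r$seed,
        "), low-support splits: ", r$flagged_low_support, "\n", sep = "")
  }
  invisible(x)
}

#' Write a machine-readable run report
#'
#' @param run An `sk_run` from [sans_run()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
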