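#' Construct a split set
#'
#' A split set is a tibble-backed container for weighted phylogenetic
#' splits over a fixed, ordered taxon list. Each split is a bipartition
#' of the taxa, stored by its *normalized side*: the side that does NOT
#' contain taxon 1. Complementary sides denote the same split, so
#' normalization makes representation unique; weights of complementary
#' patterns are merged on construction.
#'
#' @param sides List of integer vectors (taxon indices of one side of each
#'   split; either side may be given).
#' @param weight Numeric vector of non-negative split weights (number of
#'   distinct supporting k-mers).
#' @param taxa Character vector of taxon (genome) ids; order defines
#'   indices.
#' @param total_kmers Total number of distinct indexed k-mers (the `n` of
#'   bootstrap resampling); defaults to the weight sum.
#' @param filter_state One of `"none"`, `"strict"`, `"weakly"`, `"tree"`.
#' @return A tibble of class `split_set` with columns `side` (list of
#'   sorted integer vectors), `side_key` (comma-joined side, the unique
#'   id), `weight`, `trivial` (side of size 1 or `n-1`), and attributes
#'   `taxa`, `total_kmers`, `filter_state`.
#' @export
split_set <- function(sides, weight, taxa, total_kmers = NULL,
                      filter_state = "none") {
  n <- length(taxa)
  if (n < 1L) abort("empty taxon set")
  norm <- lapply(sides, normalize_side, n = n)
  bad <- vapply(norm, function(s) length(s) == 0L || length(s) == n,
                logical(1))
  if (any(bad)) abort("split side must be a proper non-empty subset of taxa")
  keys <- vapply(norm, paste, character(1), collapse = ",")
  tb <- tibble(side = norm, side_key = keys, weight = as.numeric(weight))
  tb <- dplyr::summarise(dplyr::group_by(tb, .data$side_key),
                         side = .data$side[1L],
                         weight = sum(.data$weight), .groups = "drop")
  tb$trivial <- lengths(tb$side) %in% c(1L, n - 1L)
  tb <- tb[order_splits(tb), c("side", "side_key", "weight", "trivial")]
  new_split_set(tb, taxa, total_kmers %||% sum(tb$weight), filter_state)
}

new_split_set <- function(tb, taxa, total_kmers, filter_state) {
  structure(tb,
            taxa = as.character(taxa),
            total_kmers = as.numeric(total_kmers),
            filter_state = filter_state,
            class = c("split_set", class(tibble())))
}

# deterministic ordering: decreasing weight, then smaller side, then
# lexicographic side membership (padded so index 10 sorts after 2)
order_splits <- function(tb) {
  lex <- vapply(tb$side, function(s) paste(sprintf("%09d", s), collapse = ","),
                character(1))
  order(-tb$weight, lengths(tb$side), lex)
}

# normalized side: the side not containing taxon 1
normalize_side <- function(side, n) {
  side <- sort(unique(as.integer(side)))
  if (1L %in% side) side <- setdiff(seq_len(n), side)
  side
}

#' Taxa of a split set
#' @param splits A `split_set`.
#' @return Character vector of taxon ids.
#' @export
sk_taxa <- function(splits) attr(splits, "taxa")

#' Total distinct k-mer count backing a split set
#' @param splits A `split_set`.
#' @return Numeric scalar (the bootstrap `n`).
#' @export
sk_total_kmers <- function(splits) attr(splits, "total_kmers")

#' Filter state of a split set
#' @param splits A `split_set`.
#' @return `"none"`, `"strict"`, `"weakly"` or `"tree"`.
#' @export
sk_filter_state <- function(splits) attr(splits, "filter_state")

#' Derive weighted splits from a k-mer index
#'
#' Every distinct occurrence pattern (subset of genomes sharing a set of
#' k-mers) is interpreted as one phylogenetic split whose weight is the
#' number of distinct keys with exactly that pattern. Singleton-map
#' entries yield trivial splits (one genome vs the rest). Keys present in
#' *all* genomes are phylogenetically uninformative: they contribute to
#' `total_kmers` but induce no split, as does any k-mer, at most one
#' split.
#'
#' @param index A `kmer_index` from [kmer_index()].
#' @param weighting Optional function `(weight, side_size, n_taxa) ->
#'   numeric` applied to each split's raw distinct-k-mer count (hook for
#'   alternative weightings); default: raw counts.
#' @return A `split_set` with `filter_state = "none"`.
#' @export
derive_splits <- function(index, weighting = NULL) {
  n <- length(index$genome_ids)
  pats <- c(unname(index$shared), as.character(index$singleton))
  total <- length(pats)
  if (total == 0L) {
    return(new_split_set(
      tibble(side = list(), side_key = character(0), weight = numeric(0),
             trivial = logical(0)),
      index$genome_ids, 0, "none"))
  }
  counts <- table(pats)
  pat_sets <- lapply(strsplit(names(counts), ",", fixed = TRUE), as.integer)
  full <- lengths(pat_sets) == n
  sides <- pat_sets[!full]
  w <- as.numeric(counts)[!full]
  if (length(sides) == 0L) {
    return(new_split_set(
      tibble(side = list(), side_key = character(0), weight = numeric(0),
             trivial = logical(0)),
      index$genome_ids, total, "none"))
  }
  ss <- split_set(sides, w, index$genome_ids, total_kmers = total)
  if (!is.null(weighting)) {
    tb <- tibble(side = ss$side, side_key = ss$side_key,
                 weight = vapply(seq_len(nrow(ss)), function(i)
                   weighting(ss$weight[[i]], length(ss$side[[i]]), n),
                   numeric(1)),
                 trivial = ss$trivial)
    ss <- new_split_set(tb[order_splits(tb), ], index$genome_ids, total,
                        "none")
  }
  ss
}

#' @export
print.split_set <- function(x, ...) {
  cat("<split_set> ", nrow(x), " splits (", sum(!x$trivial),
      " non-trivial) over ", length(sk_taxa(x)), " taxa; ",
      "filter=", sk_filter_state(x), "; total k-mers=",
      format(sk_total_kmers(x)), "\n", sep = "")
  NextMethod()
}

#' Tidy a split set
#'
#' @param x A `split_set`.
#' @param ... Unused.
#' @return A plain tibble with taxon names substituted into the side
#'   (`side` as a comma-joined label), plus `size`, `weight`, `trivial`
#'   and, when present, `support`.
#' @export
tidy.split_set <- function(x, ...) {
  taxa <- sk_taxa(x)
  out <- tibble(
    side = vapply(x$side, function(s) paste(taxa[s], collapse = ","),
                  character(1)),
    size = lengths(x$side),
    weight = x$weight,
    trivial = x$trivial)
  if ("support" %in% names(x)) out$support <- x$support
  out
}

#' Summarize a split set
#'
#' @param x A `split_set`.
#' @param ... Unused.
#' @return One-row tibble: taxon count, split counts, weight mass,
#'   total k-mers, filter state.
#' @export
glance.split_set <- function(x, ...) {
  tibble(n_taxa = length(sk_taxa(x)),
         n_splits = nrow(x),
         n_nontrivial = sum(!x$trivial),
         weight_sum = sum(x$weight),
         total_kmers = sk_total_kmers(x),
         filter_state = sk_filter_state(x))
}

#' Plot split weights
#'
#' Lollipop chart of split weights in filter order, trivial splits
#' dimmed; when bootstrap support has been annotated, points are colored
#' by it.
#'
#' @param object A `split_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.split_set <- function(object, ...) {
  d <- tidy(object)
  d$rank <- seq_len(nrow(d))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$weight)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$rank, yend = 0,
                                       alpha = !.data$trivial)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "split (by decreasing weight)",
                  y = "weight (distinct supporting k-mers)") +
    ggplot2::theme_minimal()
  if ("support" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$support)) +
      ggplot2::scale_colour_gradient(limits = c(0, 1), low = "firebrick",
                                     high = "steelblue")
  } else {
    p <- p + ggplot2::geom_point()
  }
  p
}
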