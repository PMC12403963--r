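#' Resample split weights for one bootstrap replicate
#'
#' Simulates drawing `n` k-mers uniformly at random with replacement from
#' the `n` distinct k-mers of the input, and re-weights every split by
#' how many draws land on its supporting k-mers.
#'
#' Two samplers are provided:
#'
#' * `"per_kmer"` (default): a split supported by `x` of the `n` k-mers
#'   receives replicate weight `Binomial(n, x/n)` — the marginal of the
#'   multinomial draw over its `x` supporters. Mean `x`, variance
#'   `x(1 - x/n)`.
#' * `"per_split"`: replicate weight `x * p` with a single
#'   `p ~ Binomial(n, 1/n)` per split (the multiplicity of one individual
#'   k-mer under the same draw). Mean `x`, variance `x^2 (1 - 1/n)`.
#'   Note that under this sampler every split, however heavy, vanishes
#'   with probability `(1 - 1/n)^n ~ 1/e` per replicate, capping
#'   attainable support near 0.63; it is retained for sensitivity
#'   analysis only.
#'
#' Splits with replicate weight 0 are dropped from the replicate. Uses
#' the current RNG state.
#'
#' @param splits A `split_set` with `total_kmers >= 1`.
#' @param method `"per_kmer"` or `"per_split"`.
#' @return A `split_set` with resampled weights.
#' @export
resample_weights <- function(splits, method = c("per_kmer", "per_split")) {
  method <- match.arg(method)
  n <- sk_total_kmers(splits)
  if (n < 1) abort("total_kmers is 0: nothing to resample")
  x <- splits$weight
  w <- if (method == "per_kmer") {
    as.numeric(rbinom(length(x), size = round(n), prob = pmin(1, x / n)))
  } else {
    x * as.numeric(rbinom(length(x), size = round(n), prob = 1 / n))
  }
  keep <- w > 0
  tb <- tibble(side = splits$side[keep], side_key = splits$side_key[keep],
               weight = w[keep], trivial = splits$trivial[keep])
  new_split_set(tb[order_splits(tb), ], sk_taxa(splits), n,
                sk_filter_state(splits))
}

#' Bootstrap support for splits
#'
#' Runs `replicates` bootstrap replicates: each resamples the split
#' weights (see [resample_weights()]), re-applies the greedy filter like
#' the original dataset, and records which splits survive. The support of
#' a split is its relative abundance among the replicates' filtered sets.
#' Support is computed for every original (pre-filter) split, so the
#' result serves both for annotating the filtered set and for consensus
#' construction.
#'
#' Per-replicate RNG streams are derived deterministically from `seed`
#' and the replicate index, so results are independent of processing
#' order (and of any worker count).
#'
#' @param splits The derived, pre-filter `split_set`.
#' @param replicates Number of replicates `N >= 1`.
#' @param seed Integer seed.
#' @param filter_mode Filter applied to each replicate (and to define the
#'   original surviving set): `"strict"`, `"weakly"` or `"tree"`.
#' @param method Resampling method, see [resample_weights()].
#' @return An object of class `bootstrap_result`: a tibble with one row
#'   per original pre-filter split (`side`, `side_key`, `weight`,
#'   `support`), and attributes `replicates`, `seed`, `filter_mode`,
#'   `method`, `taxa`.
#' @export
bootstrap_support <- function(splits, replicates = 1000L, seed = 1L,
                              filter_mode = c("strict", "weakly", "tree"),
                              method = c("per_kmer", "per_split")) {
  filter_mode <- match.arg(filter_mode)
  method <- match.arg(method)
  if (replicates < 1L) abort("replicates must be >= 1")
  rep_seeds <- with_local_seed(seed, function()
    sample.int(.Machine$integer.max - 1L, replicates))
  hits <- setNames(numeric(nrow(splits)), splits$side_key)
  for (r in seq_len(replicates)) {
    surv <- with_local_seed(rep_seeds[[r]], function() {
      rs <- resample_weights(splits, method)
      greedy_filter(rs, filter_mode)$side_key
    })
    inh <- names(hits) %in% surv
    hits[inh] <- hits[inh] + 1
  }
  structure(
    tibble(side = splits$side, side_key = splits$side_key,
           weight = splits$weight, trivial = splits$trivial,
           support = unname(hits) / replicates),
    replicates = as.integer(replicates), seed = as.integer(seed),
    filter_mode = filter_mode, method = method, taxa = sk_taxa(splits),
    class = c("bootstrap_result", class(tibble())))
}

# evaluate fn under a locally-set RNG seed, restoring the caller's state
with_local_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Annotate a filtered split set with bootstrap support
#'
#' @param splits A filtered `split_set`.
#' @param result A `bootstrap_result` over the same taxa.
#' @return `splits` with an added `support` column (NA for splits absent
#'   from the result).
#' @export
annotate_support <- function(splits, result) {
  sup <- setNames(result$support, result$side_key)
  tb <- as_tibble(splits)
  tb$support <- unname(sup[splits$side_key])
  new_split_set(tb, sk_taxa(splits), sk_total_kmers(splits),
                sk_filter_state(splits))
}

#' Flag splits with low bootstrap support
#'
#' @param result A `bootstrap_result`.
#' @param threshold Support threshold (default 0.75: splits below 75%
#'   support are flagged, the convention used for highlighting
#'   low-confidence network edges).
#' @return The result tibble with a logical `flagged` column.
#' @export
flag_low_support <- function(result, threshold = 0.75) {
  out <- as_tibble(result)
  out$flagged <- out$support < threshold
  out
}

#' Consensus split set by support threshold
#'
#' Keeps the original splits whose bootstrap support reaches `threshold`;
#' every kept split carries its *original* weight (not a resampled one).
#'
#' @param splits The `split_set` the support was computed for.
#' @param result A `bootstrap_result` over the same splits.
#' @param threshold Minimum support in `[0, 1]`.
#' @return A `split_set` restricted to the supported splits.
#' @export
consensus_splits <- function(splits, result, threshold) {
  sup <- setNames(result$support, result$side_key)
  keep <- !is.na(sup[splits$side_key]) & sup[splits$side_key] >= threshold
  tb <- tibble(side = splits$side[keep], side_key = splits$side_key[keep],
               weight = splits$weight[keep], trivial = splits$trivial[keep])
  new_split_set(tb, sk_taxa(splits), sk_total_kmers(splits),
                sk_filter_state(splits))
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", attr(x, "replicates"), " replicates, filter=",
      attr(x, "filter_mode"), ", method=", attr(x, "method"),
      ", seed=", attr(x, "seed"), "\n", sep = "")
  NextMethod()
}

#' Tidy a bootstrap result
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A plain tibble with side labels, weights and support.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  taxa <- attr(x, "taxa")
  tibble(side = vapply(x$side, function(s) paste(taxa[s], collapse = ","),
                       character(1)),
         size = lengths(x$side), weight = x$weight, trivial = x$trivial,
         support = x$support)
}

#' Summarize a bootstrap result
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return One-row tibble with replicate count and support summary.
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble(replicates = attr(x, "replicates"),
         filter_mode = attr(x, "filter_mode"),
         method = attr(x, "method"),
         n_splits = nrow(x),
         mean_support = mean(x$support),
         min_support = min(x$support))
}

#' Plot bootstrap support against split weight
#'
#' @param object A `bootstrap_result`.
#' @param threshold Flagging threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_result <- function(object, threshold = 0.75, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$support,
                                  shape = .data$trivial)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "original split weight (k-mers, log scale)",
                  y = "bootstrap support") +
    ggplot2::theme_minimal()
}
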