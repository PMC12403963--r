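#' Pairwise compatibility of two splits
#'
#' Two splits `A1|B1`, `A2|B2` over the same taxa are compatible iff at
#' least one of the four intersections `A1&A2`, `A1&B2`, `B1&A2`, `B1&B2`
#' is empty — the defining property of split sets realizable as edges of
#' a single unrooted tree.
#'
#' @param s1,s2 Integer vectors: taxon indices of one side of each split
#'   (either side).
#' @param n_taxa Number of taxa.
#' @return Logical scalar.
#' @examples
#' are_compatible(c(1, 2), c(1), 4)        # ab|cd vs a|bcd: TRUE
#' are_compatible(c(1, 2), c(1, 3), 4)     # ab|cd vs ac|bd: FALSE
#' @export
are_compatible <- function(s1, s2, n_taxa) {
  i11 <- length(intersect(s1, s2))
  a1 <- length(s1); a2 <- length(s2)
  i11 == 0L || (a1 - i11) == 0L || (a2 - i11) == 0L ||
    (n_taxa - a1 - a2 + i11) == 0L
}

#' Weak compatibility of three splits
#'
#' Three splits are weakly compatible iff no four taxa `x0, x1, x2, x3`
#' exist such that split `i` separates `{x0, xi}` from the other two —
#' i.e. no quartet on which the three splits realize all three pairings.
#' This is the triple condition defining weakly compatible split systems
#' (the class drawable as split networks). Implemented via the eight-cell
#' occupancy of the three bipartitions: a violation exists iff, for one of
#' the two parity classes of cells, all four cells of that class are
#' occupied.
#'
#' @param s1,s2,s3 Integer vectors: one side of each split.
#' @param n_taxa Number of taxa.
#' @return Logical scalar.
#' @export
are_weakly_compatible <- function(s1, s2, s3, n_taxa) {
  m1 <- m2 <- m3 <- logical(n_taxa)
  m1[s1] <- TRUE; m2[s2] <- TRUE; m3[s3] <- TRUE
  cell <- 1L + m1 + 2L * m2 + 4L * m3
  occ <- tabulate(cell, nbins = 8L) > 0L
  # cells indexed 1..8 = codes 000..111; parity classes by bit-sum parity
  odd  <- occ[c(8L, 2L, 3L, 5L)]  # 111, 100, 010, 001
  even <- occ[c(1L, 7L, 6L, 4L)]  # 000, 011, 101, 110
  !(all(odd) || all(even))
}

#' Greedily filter a split set to a compatible or weakly compatible subset
#'
#' Visits splits in order of decreasing weight (ties broken by smaller
#' side, then lexicographic side membership, for determinism) and keeps a
#' split iff adding it preserves the requested property against all
#' previously kept splits:
#'
#' * `"strict"` / `"tree"` (aliases): pairwise compatibility — the result
#'   is realizable as an unrooted tree (at most `n_taxa - 3` non-trivial
#'   splits survive).
#' * `"weakly"`: weak compatibility of every triple involving the
#'   candidate — the result is drawable as a split network.
#'
#' Trivial splits never violate either property and are always kept.
#'
#' @param splits A `split_set`.
#' @param mode `"strict"`, `"tree"` or `"weakly"`.
#' @return A `split_set` with `filter_state` set to `mode`.
#' @export
greedy_filter <- function(splits, mode = c("strict", "weakly", "tree")) {
  mode <- match.arg(mode)
  n <- length(sk_taxa(splits))
  ord <- order_splits(splits)
  sides <- splits$side[ord]
  trivial <- splits$trivial[ord]
  keep <- logical(length(sides))
  kept_nt <- list()  # non-trivial kept sides
  for (i in seq_along(sides)) {
    if (trivial[[i]]) {
      keep[[i]] <- TRUE
      next
    }
    cand <- sides[[i]]
    ok <- if (mode == "weakly") {
      weakly_admissible(cand, kept_nt, n)
    } else {
      all(vapply(kept_nt, are_compatible, logical(1), s2 = cand,
                 n_taxa = n))
    }
    if (ok) {
      keep[[i]] <- TRUE
      kept_nt[[length(kept_nt) + 1L]] <- cand
    }
  }
  tb <- tibble(side = sides[keep],
               side_key = splits$side_key[ord][keep],
               weight = splits$weight[ord][keep],
               trivial = trivial[keep])
  new_split_set(tb, sk_taxa(splits), sk_total_kmers(splits), mode)
}

# candidate is admissible under weak compatibility iff every triple
# (cand, kept_i, kept_j), i < j, is weakly compatible (trivial splits can
# never participate in a violating quartet and are skipped)
weakly_admissible <- function(cand, kept, n) {
  nk <- length(kept)
  if (nk < 2L) return(TRUE)
  for (i in seq_len(nk - 1L)) {
    for (j in (i + 1L):nk) {
      if (!are_weakly_compatible(cand, kept[[i]], kept[[j]], n)) {
        return(FALSE)
      }
    }
  }
  TRUE
}
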