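#' Realize a compatible split set as an unrooted tree
#'
#' A pairwise-compatible split set corresponds to a unique unrooted tree
#' whose internal edges are the non-trivial splits and whose pendant
#' edges are the trivial splits; split weights become branch lengths.
#' Because normalized sides all exclude taxon 1, compatibility makes them
#' a laminar family, which is realized by nesting maximal sides.
#'
#' @param splits A `split_set` whose `filter_state` is `"strict"` or
#'   `"tree"` (or any pairwise-compatible set).
#' @param support Optional numeric vector/named vector of per-split
#'   support in `[0, 1]` (named by `side_key`), written as internal node
#'   labels.
#' @return An [ape::read.tree()] `phylo` object (unrooted).
#' @export
splits_to_tree <- function(splits, support = NULL) {
  n <- length(sk_taxa(splits))
  check_pairwise_compatible(splits)
  txt <- newick_from_splits(splits, support)
  tr <- ape::read.tree(text = txt)
  tr
}

check_pairwise_compatible <- function(splits) {
  nt <- splits$side[!splits$trivial]
  n <- length(sk_taxa(splits))
  if (length(nt) >= 2L) {
    for (i in seq_len(length(nt) - 1L)) {
      for (j in (i + 1L):length(nt)) {
        if (!are_compatible(nt[[i]], nt[[j]], n)) {
          abort("split set is not pairwise compatible; run greedy_filter(mode = 'strict') first")
        }
      }
    }
  }
  invisible(TRUE)
}

# Newick text from a compatible split set. Sides excluding taxon 1 form a
# laminar family; the tree is rooted (for serialization only) at the node
# adjacent to taxon 1.
newick_from_splits <- function(splits, support = NULL) {
  taxa <- sk_taxa(splits)
  n <- length(taxa)
  nt <- splits[!splits$trivial, ]
  # pendant lengths: trivial split of taxon t>=2 has side {t}; taxon 1's
  # pendant is the side of size n-1
  pend <- numeric(n)
  for (i in which(splits$trivial)) {
    s <- splits$side[[i]]
    t <- if (length(s) == 1L) s else 1L
    pend[t] <- splits$weight[[i]]
  }
  sup <- function(key) {
    if (is.null(support)) return("")
    v <- support[key]
    if (is.na(v)) "" else format_num(v)
  }
  clusters <- nt$side[order(-lengths(nt$side))]
  cl_w <- nt$weight[order(-lengths(nt$side))]
  cl_key <- nt$side_key[order(-lengths(nt$side))]
  build <- function(members, avail) {
    # avail: indices into clusters still unplaced, all subsets of members
    out <- character(0)
    used <- integer(0)
    remaining <- members
    while (length(avail) > 0L) {
      top <- avail[[1L]]
      sub <- clusters[[top]]
      inner <- avail[-1L][vapply(avail[-1L], function(j)
        all(clusters[[j]] %in% sub), logical(1))]
      lab <- sup(cl_key[[top]])
      out <- c(out, paste0(build(sub, inner), lab, ":",
                           format_num(cl_w[[top]])))
      remaining <- setdiff(remaining, sub)
      avail <- setdiff(avail[-1L], inner)
    }
    leaves <- if (length(remaining) == 0L) character(0) else
      paste0(quote_label(taxa[remaining]), ":",
             vapply(pend[remaining], format_num, character(1)))
    paste0("(", paste(c(out, leaves), collapse = ","), ")")
  }
  paste0(build(seq_len(n), seq_along(clusters)), ";")
}

format_num <- function(x) {
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  s
}

quote_label <- function(x) {
  needs <- grepl("[ ,();:\\[\\]']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Extract the split decomposition of a tree
#'
#' Inverse of [splits_to_tree()]: every edge of an unrooted tree induces
#' one split (the tips on its far side), with the branch length as
#' weight.
#'
#' @param tree A `phylo` object.
#' @param taxa Optional taxon ordering (default: the tree's tip labels).
#' @return A `split_set` with `filter_state = "tree"`.
#' @export
tree_splits <- function(tree, taxa = NULL) {
  taxa <- taxa %||% tree$tip.label
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  tip_idx <- match(tree$tip.label, taxa)
  if (anyNA(tip_idx)) abort("tree tips not contained in `taxa`")
  wts <- tree$edge.length %||% rep(1, nrow(tree$edge))
  sides <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    below <- if (child <= n) child else
      unlist(tips_below(tree, child, n))
    sides[[e]] <- sort(tip_idx[below])
  }
  ok <- lengths(sides) >= 1L & lengths(sides) <= length(taxa) - 1L
  split_set(sides[ok], wts[ok], taxa, filter_state = "tree")
}

# tips below an internal node (simple recursion on the edge table)
tips_below <- function(tree, node, n) {
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, function(k) {
    if (k <= n) k else tips_below(tree, k, n)
  }))
}

#' Write a tree-filtered split set as Newick
#'
#' @param splits A pairwise-compatible `split_set`.
#' @param path Output file path.
#' @param support Optional `bootstrap_result` (or named numeric vector by
#'   `side_key`); supports appear as internal node labels.
#' @return `path`, invisibly.
#' @export
write_newick <- function(splits, path, support = NULL) {
  if (inherits(support, "bootstrap_result")) {
    support <- setNames(support$support, support$side_key)
  }
  txt <- newick_from_splits(splits, support)
  writeLines(txt, path)
  invisible(path)
}
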