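#' Write a split set as SplitsTree-compatible NEXUS
#'
#' Emits a NEXUS document with a `TAXA` block and a `SPLITS` block in the
#' SplitsTree 4 dialect (`st_splits`): uppercase block keywords, 1-based
#' taxon indices, one matrix row per split listing the weight, the
#' optional confidence, and the taxon indices of the normalized side.
#' When bootstrap support is given it is encoded as confidences in
#' `[0, 100]` (percent). When a label map is given, a `TRAITS` block with
#' per-taxon group and color is appended (unknown blocks are ignored by
#' NEXUS readers).
#'
#' @param splits A `split_set`.
#' @param path Output file path.
#' @param support Optional `bootstrap_result` or named numeric vector of
#'   support in `[0, 1]` keyed by `side_key`.
#' @param labels Optional `label_map` from [parse_label_files()].
#' @return `path`, invisibly.
#' @export
write_split_nexus <- function(splits, path, support = NULL, labels = NULL) {
  taxa <- sk_taxa(splits)
  n <- length(taxa)
  if (n == 0L) abort("empty taxon set")
  if (inherits(support, "bootstrap_result")) {
    support <- setNames(support$support, support$side_key)
  }
  bad <- vapply(splits$side, function(s) any(s < 1L | s > n), logical(1))
  if (any(bad)) abort("split side indices out of taxon range")
  out <- c(
    "#NEXUS",
    "",
    "BEGIN TAXA;",
    paste0("DIMENSIONS NTAX=", n, ";"),
    "TAXLABELS",
    paste0("  ", quote_label(taxa)),
    ";",
    "END;",
    "",
    "BEGIN SPLITS;",
    paste0("DIMENSIONS NTAX=", n, " NSPLITS=", nrow(splits), ";"),
    paste0("FORMAT LABELS=NO WEIGHTS=YES CONFIDENCES=",
           if (is.null(support)) "NO" else "YES", ";"),
    "MATRIX")
  rows <- vapply(seq_len(nrow(splits)), function(i) {
    conf <- if (is.null(support)) "" else {
      v <- support[splits$side_key[[i]]]
      paste0(format_num(100 * ifelse(is.na(v), 0, v)), "\t")
    }
    paste0("  ", format_num(splits$weight[[i]]), "\t", conf,
           paste(splits$side[[i]], collapse = " "), ",")
  }, character(1))
  out <- c(out, rows, ";", "END;")
  if (!is.null(labels)) {
    out <- c(out, "", nexus_traits_block(labels, taxa))
  }
  writeLines(out, path)
  invisible(path)
}

nexus_traits_block <- function(labels, taxa) {
  lm <- labels$taxon_groups
  lm <- lm[lm$taxon %in% taxa, ]
  cols <- labels$group_colors
  color_of <- setNames(cols$color, cols$group)
  c("BEGIN TRAITS;",
    paste0("DIMENSIONS NTRAITS=2;"),
    "FORMAT LABELS=YES MISSING=?;",
    "TRAITLABELS group color;",
    "MATRIX",
    vapply(taxa, function(t) {
      g <- lm$group[match(t, lm$taxon)]
      if (is.na(g)) paste0("  ", quote_label(t), " ? ?")
      else paste0("  ", quote_label(t), " ", quote_label(g), " ",
                  color_of[g])
    }, character(1)),
    ";", "END;")
}

#' Read a NEXUS splits file
#'
#' Parses the `TAXA` and `SPLITS` blocks written by
#' [write_split_nexus()] back into a `split_set`; confidences, when
#' present, are returned via the `support` column (rescaled to `[0, 1]`).
#'
#' @param path Path to a NEXUS file.
#' @return A `split_set` (with a `support` column when the file carries
#'   confidences).
#' @export
read_split_nexus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^#NEXUS", lines, ignore.case = TRUE))) {
    abort(paste0("not a NEXUS file: ", path))
  }
  taxa <- nexus_taxa(lines)
  sb <- nexus_block(lines, "SPLITS")
  has_conf <- any(grepl("CONFIDENCES\\s*=\\s*YES", sb, ignore.case = TRUE))
  mstart <- grep("^\\s*MATRIX\\s*$", sb, ignore.case = TRUE)[1L]
  if (is.na(mstart)) abort("SPLITS block has no MATRIX")
  rows <- sb[(mstart + 1L):length(sb)]
  rows <- rows[!grepl("^\\s*(;|END;?)\\s*$", rows, ignore.case = TRUE)]
  rows <- trimws(sub(",\\s*$", "", rows))
  rows <- rows[nzchar(rows)]
  fields <- strsplit(rows, "[ \t]+")
  w <- vapply(fields, function(f) as.numeric(f[[1L]]), numeric(1))
  conf <- if (has_conf)
    vapply(fields, function(f) as.numeric(f[[2L]]), numeric(1)) else NULL
  off <- if (has_conf) 2L else 1L
  sides <- lapply(fields, function(f)
    as.integer(f[(off + 1L):length(f)]))
  ss <- split_set(sides, w, taxa)
  if (has_conf) {
    # reattach support after normalization reordering
    keys <- vapply(lapply(sides, normalize_side, n = length(taxa)),
                   paste, character(1), collapse = ",")
    sup <- setNames(conf / 100, keys)
    tb <- as_tibble(ss)
    tb$support <- unname(sup[ss$side_key])
    ss <- new_split_set(tb, taxa, sk_total_kmers(ss), sk_filter_state(ss))
  }
  ss
}

nexus_block <- function(lines, name) {
  b <- grep(paste0("^\\s*BEGIN\\s+", name, "\\s*;"), lines,
            ignore.case = TRUE)
  if (length(b) == 0L) abort(paste0("no ", name, " block"))
  e <- grep("^\\s*END\\s*;", lines, ignore.case = TRUE)
  e <- e[e > b[1L]][1L]
  lines[(b[1L] + 1L):(e - 1L)]
}

nexus_taxa <- function(lines) {
  tb <- nexus_block(lines, "TAXA")
  i <- grep("^\\s*TAXLABELS", tb, ignore.case = TRUE)[1L]
  j <- grep("^\\s*;", tb)
  j <- j[j > i][1L]
  labs <- trimws(tb[(i + 1L):(j - 1L)])
  labs <- labs[nzchar(labs)]
  gsub("''", "'", sub("^'(.*)'$", "\\1", labs))
}

#' Write a split set as plain TSV
#'
#' One line per split: the weight, then the genome ids of the normalized
#' side, tab-separated. Parseable, diffable, and round-trips exactly
#' (weights printed with full precision).
#'
#' @param splits A `split_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_splits_tsv <- function(splits, path) {
  taxa <- sk_taxa(splits)
  lines <- vapply(seq_len(nrow(splits)), function(i) {
    paste(c(sprintf("%.17g", splits$weight[[i]]),
            taxa[splits$side[[i]]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain splits TSV
#'
#' @param path Path to a file written by [write_splits_tsv()].
#' @param taxa Character vector of taxon ids (the TSV itself does not fix
#'   taxon order).
#' @return A `split_set`.
#' @export
read_splits_tsv <- function(path, taxa) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  w <- vapply(fields, function(f) as.numeric(f[[1L]]), numeric(1))
  sides <- lapply(fields, function(f) {
    idx <- match(f[-1L], taxa)
    if (anyNA(idx)) abort(paste0("unknown taxon in ", path, ": ",
                                 f[-1L][is.na(idx)][1L]))
    idx
  })
  split_set(sides, w, taxa)
}

#' F1 agreement between two split sets
#'
#' Robinson–Foulds-style comparison on non-trivial splits: precision is
#' the fraction of the estimated non-trivial splits present in the
#' reference, recall the fraction of reference non-trivial splits
#' recovered, and F1 their harmonic mean. Trivial splits are present in
#' every phylogeny and are excluded. Sharing is judged on normalized
#' sides after harmonizing taxon order to the estimate's.
#'
#' @param estimated A `split_set`.
#' @param reference A `split_set` or a `phylo` tree (its split
#'   decomposition is used).
#' @return One-row tibble with `precision`, `recall`, `f1`,
#'   `n_estimated`, `n_reference`, `n_shared` (non-trivial counts).
#' @export
f1_against_reference <- function(estimated, reference) {
  taxa <- sk_taxa(estimated)
  if (inherits(reference, "phylo")) {
    reference <- tree_splits(reference, taxa = taxa)
  } else {
    rt <- sk_taxa(reference)
    if (!setequal(rt, taxa)) {
      abort(paste0("taxa mismatch: only in estimated: ",
                   paste(setdiff(taxa, rt), collapse = ","),
                   "; only in reference: ",
                   paste(setdiff(rt, taxa), collapse = ",")))
    }
    if (!identical(rt, taxa)) {
      # re-express reference sides in the estimate's taxon order
      sides <- lapply(reference$side, function(s) match(rt[s], taxa))
      reference <- split_set(sides, reference$weight, taxa,
                             sk_total_kmers(reference),
                             sk_filter_state(reference))
    }
  }
  est <- estimated$side_key[!estimated$trivial]
  ref <- reference$side_key[!reference$trivial]
  shared <- length(intersect(est, ref))
  precision <- if (length(est) == 0L) NA_real_ else shared / length(est)
  recall <- if (length(ref) == 0L) NA_real_ else shared / length(ref)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    0 else 2 * precision * recall / (precision + recall)
  if (shared == 0L && (length(est) == 0L || length(ref) == 0L)) {
    f1 <- if (length(est) == 0L && length(ref) == 0L) 1 else 0
  }
  tibble(precision = precision, recall = recall, f1 = f1,
         n_estimated = length(est), n_reference = length(ref),
         n_shared = shared)
}

#' Parse taxon-group label and group-color files
#'
#' Both files are two-column, tab-separated. The first maps taxa to group
#' names (partial labeling allowed; a label for an unknown taxon is
#' dropped with a warning; on duplicate taxon lines the last assignment
#' wins, with a warning). The second maps groups to colors; when absent,
#' colors are assigned from a fixed palette in group first-appearance
#' order.
#'
#' @param labels_path Path to the taxon-to-group TSV.
#' @param colors_path Optional path to the group-to-color TSV.
#' @param taxa Character vector of the run's taxon ids (for validation);
#'   `NULL` skips the unknown-taxon check.
#' @return A list of class `label_map` with tibbles `taxon_groups`
#'   (`taxon`, `group`) and `group_colors` (`group`, `color`).
#' @export
parse_label_files <- function(labels_path, colors_path = NULL, taxa = NULL) {
  tg <- read_two_column_tsv(labels_path, c("taxon", "group"))
  if (!is.null(taxa)) {
    unknown <- !(tg$taxon %in% taxa)
    if (any(unknown)) {
      warn(paste0("label file names unknown taxa (ignored): ",
                  paste(unique(tg$taxon[unknown]), collapse = ", ")))
      tg <- tg[!unknown, ]
    }
  }
  if (anyDuplicated(tg$taxon)) {
    warn("duplicate taxon labels; last assignment wins")
    tg <- tg[!duplicated(tg$taxon, fromLast = TRUE), ]
  }
  groups <- unique(tg$group)
  if (!is.null(colors_path)) {
    gc <- read_two_column_tsv(colors_path, c("group", "color"))
    gc <- gc[!duplicated(gc$group, fromLast = TRUE), ]
    missing <- setdiff(groups, gc$group)
    if (length(missing) > 0L) {
      gc <- dplyr::bind_rows(gc, tibble(group = missing,
                                        color = auto_palette(missing)))
    }
  } else {
    gc <- tibble(group = groups, color = auto_palette(groups))
  }
  structure(list(taxon_groups = tg, group_colors = gc),
            class = "label_map")
}

# fixed qualitative palette, recycled in first-appearance order
auto_palette <- function(groups) {
  pal <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
           "#e6ab02", "#a6761d", "#666666")
  pal[(seq_along(groups) - 1L) %% length(pal) + 1L]
}

read_two_column_tsv <- function(path, names) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nbad <- lengths(fields) != 2L
  if (any(nbad)) {
    abort(paste0(path, " line ", keep[nbad][1L],
                 ": expected 2 tab-separated columns"))
  }
  out <- tibble(a = vapply(fields, `[[`, character(1), 1L),
                b = vapply(fields, `[[`, character(1), 2L))
  names(out) <- names
  out
}
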