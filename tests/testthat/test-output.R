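quartet_set <- function() {
  split_set(c(list(c(3, 4)), as.list(1:4)), c(2, 1, 1, 1, 1),
            taxa = c("a", "b", "c", "d"), total_kmers = 10,
            filter_state = "strict")
}

test_that("NEXUS output has the declared dimensions and round-trips", {
  ss <- quartet_set()
  f <- withr::local_tempfile(fileext = ".nex")
  write_split_nexus(ss, f)
  txt <- readLines(f)
  expect_equal(txt[1], "#NEXUS")
  expect_true(any(grepl("DIMENSIONS NTAX=4 NSPLITS=5;", txt)))
  back <- read_split_nexus(f)
  expect_equal(sk_taxa(back), sk_taxa(ss))
  expect_setequal(back$side_key, ss$side_key)
  expect_equal(weights_by_side(back)[ss$side_key],
               weights_by_side(ss)[ss$side_key])
})

test_that("NEXUS confidences carry bootstrap support in percent", {
  ss <- quartet_set()
  sup <- setNames(c(0.92, 1, 1, 1, 0.5),
                  ss$side_key)
  f <- withr::local_tempfile(fileext = ".nex")
  write_split_nexus(ss, f, support = sup)
  txt <- readLines(f)
  expect_true(any(grepl("CONFIDENCES=YES", txt)))
  expect_true(any(grepl("\t92\t", txt)))
  back <- read_split_nexus(f)
  expect_equal(unname(back$support[match(names(sup), back$side_key)]),
               unname(sup), tolerance = 1e-9)
})

test_that("label and color files attach a traits block", {
  ss <- quartet_set()
  dir <- withr::local_tempdir()
  lf <- file.path(dir, "labels.tsv")
  writeLines(c("a\tgroup1", "b\tgroup1", "c\tgroup2"), lf)
  cf <- file.path(dir, "colors.tsv")
  writeLines("group1\t#ff0000", cf)
  lm <- parse_label_files(lf, cf, taxa = sk_taxa(ss))
  expect_equal(nrow(lm$taxon_groups), 3)
  expect_equal(lm$group_colors$color[lm$group_colors$group == "group1"],
               "#ff0000")
  # group2 had no user color: automatic palette
  expect_true(nzchar(lm$group_colors$color[lm$group_colors$group == "group2"]))
  f <- file.path(dir, "out.nex")
  write_split_nexus(ss, f, labels = lm)
  expect_true(any(grepl("BEGIN TRAITS;", readLines(f))))
})

test_that("label parsing enforces the documented error and tie rules", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  writeLines("onlyonecolumn", bad)
  expect_error(parse_label_files(bad), "2 tab-separated columns")
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("a\tg1", "a\tg2", "zz\tg1"), dup)
  expect_warning(expect_warning(
    lm <- parse_label_files(dup, taxa = c("a", "b")),
    "unknown taxa"), "last assignment wins")
  expect_equal(lm$taxon_groups$group[lm$taxon_groups$taxon == "a"], "g2")
})

test_that("splits TSV round-trips weights and sides exactly", {
  withr::with_seed(31, {
    ss <- random_split_set(6, 7)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_splits_tsv(ss, f)
    back <- read_splits_tsv(f, taxa = sk_taxa(ss))
    expect_setequal(back$side_key, ss$side_key)
    expect_identical(weights_by_side(back)[sort(ss$side_key)],
                     weights_by_side(ss)[sort(ss$side_key)])
  })
})

test_that("Newick output is read by an independent parser with matching splits", {
  sim <- simulate_genomes(n_taxa = 6, seq_length = 2000, sub_prob = 0.02,
                          seed = 41)
  run <- sans_run(sim$sequences, k = 15, filter = "strict")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(run$splits, f)
  tr <- ape::read.tree(f)   # third-party parser accepts it
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, sk_taxa(run$splits))
  # its split decomposition (via an independent library) matches
  sp <- phangorn::as.splits(ape::unroot(tr))
  taxa <- sk_taxa(run$splits)
  keys <- vapply(sp, function(s) {
    side <- match(attr(sp, "labels")[s], taxa)
    if (1L %in% side) side <- setdiff(seq_along(taxa), side)
    paste(sort(side), collapse = ",")
  }, character(1))
  nt <- run$splits$side_key[!run$splits$trivial]
  expect_true(all(nt %in% keys))
})

test_that("F1 agreement follows precision/recall closed forms", {
  withr::with_seed(37, {
    ref_tr <- ape::rtree(8)
    ref <- tree_splits(ref_tr)
    expect_equal(f1_against_reference(ref, ref)$f1, 1)
    # drop one of the 5 non-trivial splits
    nt_idx <- which(!ref$trivial)
    keep <- setdiff(seq_len(nrow(ref)), nt_idx[1])
    est <- split_set(ref$side[keep], ref$weight[keep], sk_taxa(ref))
    r <- f1_against_reference(est, ref)
    expect_equal(r$precision, 1)
    expect_equal(r$recall, 0.8)
    expect_equal(r$f1, 8 / 9)
    # swapping arguments swaps precision and recall, F1 invariant
    r2 <- f1_against_reference(ref, est)
    expect_equal(r2$precision, r$recall)
    expect_equal(r2$recall, r$precision)
    expect_equal(r2$f1, r$f1)
    # disjoint non-trivial splits
    a <- split_set(list(c(2, 3)), 1, taxa = letters[1:5])
    b <- split_set(list(c(4, 5)), 1, taxa = letters[1:5])
    expect_equal(f1_against_reference(a, b)$f1, 0)
    # taxa mismatch errors informatively
    cset <- split_set(list(c(2, 3)), 1, taxa = letters[2:6])
    expect_error(f1_against_reference(a, cset), "taxa mismatch")
  })
})
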