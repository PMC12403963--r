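three_genome_index <- function() {
  # patterns: {1,2} twice, {3} once, {1,2,3} once (uninformative)
  idx <- structure(list(
    k = 3L, m = 8L, alphabet = "dna", genome_ids = c("a", "b", "c"),
    singleton = c(GGG = 3L),
    shared = c(AAA = "1,2", CCC = "1,2", ACG = "1,2,3")),
    class = "kmer_index")
  idx
}

test_that("derive_splits counts occurrence patterns and drops full-set patterns", {
  ss <- derive_splits(three_genome_index())
  expect_equal(sk_total_kmers(ss), 4)
  w <- weights_by_side(ss)
  expect_equal(unname(w[["3"]]), 1 + 2)  # {1,2} normalizes to side {3}
  # the {1,2} pattern and the singleton {3} pattern are the SAME split
  expect_equal(nrow(ss), 1)
  expect_true(ss$trivial[[1]])
  # conservation: split weights + full-set patterns = total k-mers
  expect_equal(sum(ss$weight) + 1, sk_total_kmers(ss))
})

test_that("derived split weights equal the oracle pattern histogram", {
  withr::with_seed(13, {
    for (rep in 1:4) {
      sim <- simulate_genomes(n_taxa = 5, seq_length = 1200,
                              sub_prob = 0.04, seed = sample(1e6, 1))
      idx <- kmer_index(sim$sequences, k = 9)
      ss <- derive_splits(idx)
      ora <- oracle_split_weights(oracle_index(as.list(sim$sequences), 9), 5)
      expect_mapequal(as.list(weights_by_side(ss)), as.list(ora))
      expect_equal(sk_total_kmers(ss),
                   length(oracle_index(as.list(sim$sequences), 9)))
    }
  })
})

test_that("normalization merges complementary sides and rejects degenerate ones", {
  ss <- split_set(list(c(1, 2), c(3, 4)), c(5, 7), taxa = letters[1:4])
  expect_equal(nrow(ss), 1)       # ab|cd given from both sides
  expect_equal(ss$weight, 12)
  expect_equal(ss$side[[1]], c(3L, 4L))  # side excluding taxon 1
  expect_error(split_set(list(1:4), 1, taxa = letters[1:4]), "proper")
  expect_error(split_set(list(integer(0)), 1, taxa = letters[1:4]),
               "proper")
})

test_that("pairwise compatibility matches the exhaustive intersection oracle", {
  expect_true(are_compatible(c(1, 2), c(1), 4))
  expect_false(are_compatible(c(1, 2), c(1, 3), 4))
  withr::with_seed(17, {
    n <- 5
    for (rep in 1:200) {
      s1 <- sort(sample(n, sample(1:(n - 1), 1)))
      s2 <- sort(sample(n, sample(1:(n - 1), 1)))
      expect_equal(are_compatible(s1, s2, n), oracle_compatible(s1, s2, n))
    }
  })
})

test_that("weak compatibility matches the quartet-enumeration oracle", {
  # the three splits of a quartet realize all three pairings on
  # {a,b,c,d}: that IS the forbidden configuration
  expect_false(are_weakly_compatible(c(1, 2), c(1, 3), c(1, 4), 4))
  expect_false(oracle_weakly(c(1, 2), c(1, 3), c(1, 4), 4))
  # any triple of pairwise-compatible splits is weakly compatible
  expect_true(are_weakly_compatible(c(1, 2), c(1, 2, 3), c(4, 5), 6))
  # triples containing trivial splits never violate
  expect_true(are_weakly_compatible(c(1, 2), c(1, 3), c(4), 4))
  withr::with_seed(19, {
    n <- 6
    for (rep in 1:150) {
      s <- lapply(1:3, function(i) sort(sample(n, sample(1:(n - 1), 1))))
      expect_equal(are_weakly_compatible(s[[1]], s[[2]], s[[3]], n),
                   oracle_weakly(s[[1]], s[[2]], s[[3]], n),
                   label = paste(sapply(s, paste, collapse = ","),
                                 collapse = " | "))
    }
  })
})

test_that("greedy filter keeps the heavier of two incompatible splits", {
  ss <- split_set(list(c(1, 2), c(1, 3)), c(5, 3), taxa = letters[1:4])
  out <- greedy_filter(ss, "strict")
  expect_equal(out$side_key, paste(c(3, 4), collapse = ","))  # cd = ab|cd
  # an already-compatible set passes unchanged
  ss2 <- split_set(list(c(2, 3), c(2, 3, 4), 2, 3, 4, 5, c(2, 3, 4, 5)),
                   c(9, 4, 1, 1, 1, 1, 1), taxa = letters[1:5])
  out2 <- greedy_filter(ss2, "strict")
  expect_setequal(out2$side_key, ss2$side_key)
  # idempotence
  expect_equal(greedy_filter(out2, "strict")$side_key, out2$side_key)
  expect_error(greedy_filter(ss, "bogus"))
})

test_that("filtered sets satisfy their property exhaustively and match a reference greedy", {
  withr::with_seed(23, {
    for (rep in 1:12) {
      n <- sample(4:6, 1)
      ss <- random_split_set(n, sample(4:10, 1))
      for (mode in c("strict", "weakly")) {
        out <- greedy_filter(ss, mode)
        expect_true(all(out$side_key %in% ss$side_key))
        expect_setequal(out$side_key, oracle_greedy(ss, mode, n))
        nt <- out$side[!out$trivial]
        if (mode == "strict") {
          expect_lte(length(nt), n - 3)
          if (length(nt) >= 2) {
            for (i in 1:(length(nt) - 1)) for (j in (i + 1):length(nt)) {
              expect_true(oracle_compatible(nt[[i]], nt[[j]], n))
            }
          }
        } else if (length(nt) >= 3) {
          combs <- utils::combn(length(nt), 3)
          for (c_i in seq_len(ncol(combs))) {
            expect_true(oracle_weakly(nt[[combs[1, c_i]]],
                                      nt[[combs[2, c_i]]],
                                      nt[[combs[3, c_i]]], n))
          }
        }
        # idempotence
        expect_setequal(greedy_filter(out, mode)$side_key, out$side_key)
      }
    }
  })
})

test_that("compatible split sets realize as trees and round-trip", {
  # trivial splits only: star tree
  star <- split_set(as.list(1:4), rep(1, 4), taxa = letters[1:4],
                    filter_state = "strict")
  tr <- splits_to_tree(star)
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 1)
  # quartet: single internal edge
  q <- split_set(c(list(c(3, 4)), as.list(1:4)), c(2, 1, 1, 1, 1),
                 taxa = letters[1:4], filter_state = "strict")
  qt <- splits_to_tree(q)
  rt <- f1_against_reference(q, qt)
  expect_equal(rt$f1, 1)
  # random compatible sets (from random trees) round-trip exactly
  withr::with_seed(29, {
    for (rep in 1:5) {
      tr0 <- ape::rtree(sample(4:8, 1))
      ss <- tree_splits(tr0)
      tr1 <- splits_to_tree(ss)
      ss1 <- tree_splits(tr1, taxa = sk_taxa(ss))
      expect_setequal(ss1$side_key, ss$side_key)
      w0 <- weights_by_side(ss); w1 <- weights_by_side(ss1)
      expect_equal(w1[sort(names(w1))], w0[sort(names(w0))],
                   tolerance = 1e-10)
    }
  })
  # incompatible input is a contract violation
  bad <- split_set(list(c(1, 2), c(1, 3)), c(2, 2), taxa = letters[1:4])
  expect_error(splits_to_tree(bad), "not pairwise compatible")
})

test_that("tidy, glance and autoplot work on split sets", {
  ss <- derive_splits(three_genome_index())
  td <- tidy(ss)
  expect_named(td, c("side", "size", "weight", "trivial"))
  expect_equal(td$side, "c")
  g <- glance(ss)
  expect_equal(g$n_taxa, 3)
  expect_equal(g$filter_state, "none")
  expect_s3_class(autoplot(ss), "ggplot")
})
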