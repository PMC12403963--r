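two_split_fixture <- function(total = 1000) {
  split_set(list(c(2, 3), c(3, 4)), c(200, 150), taxa = letters[1:5],
            total_kmers = total)
}

test_that("degenerate resampling cases behave as the model dictates", {
  # n = 1, single split with x = 1: Binomial(1, 1) = 1 always
  ss <- split_set(list(2), 1, taxa = c("a", "b"), total_kmers = 1)
  for (m in c("per_kmer", "per_split")) {
    rs <- resample_weights(ss, method = m)
    expect_equal(rs$weight, 1)
  }
  empty <- split_set(list(2), 1, taxa = c("a", "b"), total_kmers = 0)
  expect_error(resample_weights(empty), "nothing to resample")
})

test_that("resampled weights match closed-form binomial moments", {
  x <- 100; n <- 1e6; draws <- 2000
  ss <- split_set(list(c(2, 3)), x, taxa = letters[1:4], total_kmers = n)
  for (m in c("per_kmer", "per_split")) {
    v_theory <- if (m == "per_kmer") n * (x / n) * (1 - x / n) else
      x^2 * n * (1 / n) * (1 - 1 / n)
    ws <- withr::with_seed(101, vapply(seq_len(draws), function(i) {
      rs <- resample_weights(ss, method = m)
      if (nrow(rs) == 0) 0 else rs$weight
    }, numeric(1)))
    se <- sqrt(v_theory / draws)
    expect_lt(abs(mean(ws) - x), 3 * se)
    expect_lt(abs(stats::var(ws) - v_theory) / v_theory, 0.35)
  }
})

test_that("support values are frequencies with the right degenerate limits", {
  ss <- two_split_fixture()
  b1 <- bootstrap_support(ss, replicates = 1, seed = 4)
  expect_true(all(b1$support %in% c(0, 1)))
  b <- bootstrap_support(ss, replicates = 50, seed = 4)
  expect_true(all(b$support >= 0 & b$support <= 1))
  expect_equal(attr(b, "replicates"), 50L)
})

test_that("identical seeds reproduce support exactly", {
  ss <- two_split_fixture()
  b1 <- bootstrap_support(ss, replicates = 40, seed = 7)
  b2 <- bootstrap_support(ss, replicates = 40, seed = 7)
  expect_identical(b1$support, b2$support)
  # different seeds draw different replicate weight sequences
  w1 <- withr::with_seed(7, resample_weights(ss)$weight)
  w2 <- withr::with_seed(8, resample_weights(ss)$weight)
  expect_false(identical(w1, w2))
})

test_that("support is invariant under consistent taxon relabeling", {
  perm <- c(3L, 1L, 2L, 5L, 4L)  # new index of old taxon i
  ss <- two_split_fixture()
  sides_p <- lapply(ss$side, function(s) sort(perm[s]))
  ss_p <- split_set(sides_p, ss$weight, taxa = letters[1:5][order(perm)],
                    total_kmers = sk_total_kmers(ss))
  b <- bootstrap_support(ss, replicates = 30, seed = 12)
  b_p <- bootstrap_support(ss_p, replicates = 30, seed = 12)
  # compare by taxon-name side labels
  lab <- sort(tidy(b)$support)
  lab_p <- sort(tidy(b_p)$support)
  expect_equal(lab, lab_p)
})

test_that("a conflicting low-weight split earns lower support and consensus drops it", {
  # heavy compatible backbone + one light conflicting split
  ss <- split_set(c(list(c(2, 3), c(4, 5), c(2, 4))), c(300, 280, 20),
                  taxa = letters[1:5], total_kmers = 2000)
  b <- bootstrap_support(ss, replicates = 100, seed = 3,
                         filter_mode = "strict")
  sup <- setNames(b$support, b$side_key)
  expect_gt(min(sup[c("2,3", "4,5")]), sup[["2,4"]])
  thr <- (min(sup[c("2,3", "4,5")]) + sup[["2,4"]]) / 2
  cons <- consensus_splits(ss, b, thr)
  expect_setequal(cons$side_key, c("2,3", "4,5"))
  # kept splits carry their ORIGINAL weights
  expect_equal(sort(cons$weight), c(280, 300))
  # threshold 0 keeps everything
  expect_equal(nrow(consensus_splits(ss, b, 0)), nrow(ss))
})

test_that("flagging marks exactly the splits below threshold", {
  ss <- two_split_fixture()
  b <- bootstrap_support(ss, replicates = 60, seed = 9)
  fl <- flag_low_support(b, 0.75)
  expect_equal(fl$flagged, b$support < 0.75)
  ann <- annotate_support(greedy_filter(ss, "strict"), b)
  expect_true("support" %in% names(ann))
  expect_s3_class(autoplot(b), "ggplot")
  expect_equal(glance(b)$replicates, 60L)
})
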