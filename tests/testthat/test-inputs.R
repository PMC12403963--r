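test_that("plain input lists pass through defaults and derive ids from basenames", {
  dir <- withr::local_tempdir()
  files <- vapply(c("gA", "gB", "gC"), function(id) {
    f <- file.path(dir, paste0(id, ".fasta"))
    writeLines(c(paste0(">", id), "ACGTACGT"), f)
    f
  }, character(1))
  lst <- file.path(dir, "list.txt")
  writeLines(files, lst)
  specs <- parse_input_list(lst, abundance_min = 1)
  expect_s3_class(specs, "sk_inputs")
  expect_equal(specs$genome_id, c("gA", "gB", "gC"))
  expect_equal(specs$abundance_min, rep(1L, 3))
  expect_equal(specs$seq_kind, rep("dna", 3))
})

test_that("file-of-files lines carry multiple paths and per-genome thresholds", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "reads_1.fq.gz")
  f2 <- file.path(dir, "reads_2.fq.gz")
  for (f in c(f1, f2)) {
    con <- gzfile(f, "wt")
    writeLines(c("@r1", "ACGT", "+", "IIII"), con)
    close(con)
  }
  asm <- file.path(dir, "asm.fasta")
  writeLines(c(">a", "ACGTACGT"), asm)
  lst <- file.path(dir, "list.txt")
  writeLines(c("# mixed reads and assembly",
               "gD : reads_1.fq.gz ; reads_2.fq.gz ! 3",
               paste0("asm : ", asm)), lst)
  specs <- parse_input_list(lst, abundance_min = 1)
  expect_equal(specs$genome_id, c("gD", "asm"))
  expect_length(specs$paths[[1]], 2)
  expect_equal(specs$abundance_min, c(3L, 1L))
})

test_that("degenerate and malformed lists fail fast with useful errors", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.txt")
  writeLines(character(0), empty)
  expect_error(parse_input_list(empty), "no inputs")

  f <- file.path(dir, "g.fasta")
  writeLines(c(">g", "ACGT"), f)
  dup <- file.path(dir, "dup.txt")
  writeLines(c(paste0("x : ", f), paste0("x : ", f)), dup)
  expect_error(parse_input_list(dup), "duplicate genome id")

  badmin <- file.path(dir, "badmin.txt")
  writeLines(paste0("x : ", f, " ! 0"), badmin)
  expect_error(parse_input_list(badmin), ">= 1")

  gone <- file.path(dir, "gone.txt")
  writeLines(file.path(dir, "nothere.fasta"), gone)
  expect_error(parse_input_list(gone), "not readable")
})

test_that("file-of-files lists round-trip through write_input_list", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "g.fasta")
  writeLines(c(">g", "ACGT"), f)
  lst <- file.path(dir, "list.txt")
  writeLines(c(paste0("a : ", f, " ! 2"), paste0("b : ", f, " ; ", f)), lst)
  specs <- parse_input_list(lst)
  out <- file.path(dir, "rt.txt")
  write_input_list(specs, out)
  expect_equal(parse_input_list(out), specs)
})

test_that("read_sequences streams FASTA and FASTQ identically through gzip", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "two.fasta")
  writeLines(c(">s1 first", "acgtacgt", ">s2", "TTTTnACGT"), fa)
  fagz <- file.path(dir, "two.fasta.gz")
  con <- gzfile(fagz, "wt")
  writeLines(readLines(fa), con)
  close(con)
  specs <- input_table(list(fa, fagz), genome_id = c("plain", "gz"))
  plain <- read_sequences(specs, "plain")
  gz <- read_sequences(specs, "gz")
  expect_equal(nrow(plain), 2)
  expect_equal(plain$residues, c("ACGTACGT", "TTTTNACGT"))  # uppercased
  expect_equal(plain$residues, gz$residues)
  expect_equal(plain$header, gz$header)

  fq <- file.path(dir, "reads.fastq")
  n <- 100
  writeLines(as.vector(rbind(paste0("@r", 1:n), strrep("ACGT", 5), "+",
                             strrep("I", 20))), fq)
  rec <- read_sequences(input_table(list(fq), genome_id = "r"))
  expect_equal(nrow(rec), n)
  expect_true(all(rec$residues == strrep("ACGT", 5)))
})

test_that("U is read as T in DNA mode and malformed files are attributed", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "rna.fasta")
  writeLines(c(">r", "ACGU"), fa)
  rec <- read_sequences(input_table(list(fa), genome_id = "r"))
  expect_equal(rec$residues, "ACGT")

  bad <- file.path(dir, "bad.txt")
  writeLines("just text, no header", bad)
  expect_error(read_sequences(input_table(list(bad), genome_id = "b")),
               "malformed|neither")
})
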