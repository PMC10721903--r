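# FASTA / hit-table I/O, query coverage, Smith-Waterman.

test_that("read_fasta round-trips, normalises case and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">a", "acgt"), f)
  x <- read_fasta(f)
  expect_identical(setNames(as.character(x), names(x)), c(a = "ACGT"))
  expect_identical(attr(x, "moltype"), "dna")

  writeLines(c(">a desc text", "ACGTAC", ">b", "GGG", "CCC"), f)
  x <- read_fasta(f)
  expect_identical(names(x), c("a", "b")) # order preserved, header trimmed
  expect_identical(unname(as.character(x)), c("ACGTAC", "GGGCCC"))

  # full round trip including wrapping
  set.seed(1)
  y <- seq_set(setNames(vapply(1:5, function(i) random_dna_str(137), ""),
                        paste0("s", 1:5)), "dna")
  f2 <- withr::local_tempfile(fileext = ".fna")
  write_fasta(y, f2, width = 60)
  expect_identical(as.character(read_fasta(f2)), as.character(y))

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  file.create(f3 <- withr::local_tempfile())
  expect_warning(x0 <- read_fasta(f3), "empty")
  expect_length(x0, 0)
})

test_that("seq_set validates alphabet and ids", {
  expect_error(seq_set(c(a = "ACGZ"), "dna"), "invalid dna")
  expect_error(seq_set(c(a = "")), "empty")
  expect_error(seq_set("ACGT"), "non-empty ids")
  expect_identical(attr(seq_set(c(p = "MKV")), "moltype"), "protein")
})

test_that("read_hits parses 12/13 column tables and reports bad rows", {
  row12 <- paste(c("r1", "v1", "98.5", "150", "2", "0", "1", "150", "10",
                   "159", "1e-50", "280"), collapse = "\t")
  row13 <- paste(c(strsplit(row12, "\t")[[1]], "150"), collapse = "\t")
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(row12, f)
  h <- read_hits(f)
  expect_true(is.na(h$qlen))
  expect_equal(h$pident, 98.5)

  writeLines(row13, f)
  h <- read_hits(f)
  expect_equal(h$qlen, 150)

  writeLines(c(row13, sub("98.5", "abc", row13)), f)
  expect_error(read_hits(f), "line\\(s\\) 2")

  writeLines("a\tb\tc", f)
  expect_error(read_hits(f), "12 or 13")
})

test_that("write_hits/read_hits round-trip the tiny community tables", {
  com <- get_tiny_com()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(com$hits_amg, f)
  back <- read_hits(f)
  expect_equal(back$bitscore, com$hits_amg$bitscore)
  expect_equal(back$qseqid, com$hits_amg$qseqid)
})

test_that("query_coverage follows qcovhsp semantics and clamps", {
  h <- data.frame(qseqid = c("a", "b", "c"), qstart = c(1, 11, 1),
                  qend = c(100, 60, 85), qlen = c(100, 100, 100))
  expect_equal(query_coverage(h), c(100, 50, 85))
  # resolution through the lookup + missing-length error
  h$qlen <- NA_real_
  expect_equal(query_coverage(h, c(a = 200, b = 100, c = 100)),
               c(50, 50, 85))
  expect_error(query_coverage(h), "lookup")
  expect_error(query_coverage(h, c(a = 200)), "no query length")
  # monotone in aligned span, never above 100
  spans <- t(vapply(1:50, function(i) {
    qe <- sample(5:100, 1)
    c(qe, query_coverage(data.frame(qseqid = "x", qstart = 1, qend = qe,
                                    qlen = 100)))
  }, numeric(2)))
  expect_true(all(diff(spans[order(spans[, 1]), 2]) >= 0))
  expect_true(all(spans[, 2] <= 100))
})

test_that("smith_waterman: exact, reverse-strand and error cases", {
  h <- smith_waterman(c(q = "ACGT"), c(s = "ACGT"), moltype = "dna")
  expect_equal(h$score, 4)
  expect_equal(h$pident, 100)
  expect_equal(h$length, 4)
  expect_identical(h$strand, "+")

  h <- smith_waterman(c(q = "AAAA"), c(s = "TTTT"), moltype = "dna")
  expect_identical(h$strand, "-")
  expect_equal(h$score, 4)
  expect_equal(h$mismatch, 0)

  expect_error(
    smith_waterman(seq_set(c(q = "ACGT"), "dna"),
                   seq_set(c(p = "MKVL"), "protein")),
    "moltype mismatch")
  expect_error(
    smith_waterman(c(q = paste(rep("A", 501), collapse = "")),
                   c(s = "AAA"), moltype = "dna"),
    "short queries")
  # no positive-scoring alignment
  expect_null(smith_waterman(c(q = "AAAA"), c(s = "CCCC"),
                             moltype = "protein"))
})

test_that("smith_waterman matches the exhaustive oracle on small inputs", {
  set.seed(7)
  for (i in 1:40) {
    q <- random_dna_str(sample(2:8, 1))
    s <- random_dna_str(sample(4:12, 1))
    ora_f <- sw_oracle_score(q, s)
    ora_r <- sw_oracle_score(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(q))), s)
    h <- smith_waterman(setNames(q, "q"), setNames(s, "s"), moltype = "dna")
    best <- max(ora_f, ora_r)
    if (best <= 0) {
      expect_null(h)
    } else {
      expect_equal(h$score, best, info = paste(q, s))
    }
  }
})

test_that("smith_waterman agrees with Biostrings pairwiseAlignment scores", {
  set.seed(11)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:25) {
    q <- random_dna_str(sample(10:60, 1))
    s <- random_dna_str(sample(50:300, 1))
    ref_f <- Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    ref_r <- Biostrings::pairwiseAlignment(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(q))),
      s, type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    h <- smith_waterman(setNames(q, "q"), setNames(s, "s"), moltype = "dna")
    expect_equal(h$score, max(ref_f, ref_r, 0))
  }
})

test_that("smith_waterman score is symmetric for equal-length exact matches", {
  set.seed(3)
  for (i in 1:10) {
    x <- random_dna_str(20)
    a <- smith_waterman(setNames(x, "a"), setNames(x, "b"), moltype = "dna")
    b <- smith_waterman(setNames(x, "b"), setNames(x, "a"), moltype = "dna")
    expect_equal(a$score, b$score)
    expect_equal(a$score, 20)
  }
})

test_that("config round-trips through JSON with paper-default thresholds", {
  cfg <- default_config(seed = 9)
  expect_equal(cfg$network$max_evalue, 1e-5)
  expect_equal(cfg$network$min_bitscore, 50)
  expect_equal(cfg$abundance$species$min_identity, 95)
  expect_equal(cfg$host$wish$window, c(-1.30, -1.20))
  f <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$host$trna$min_aln, 60)
  expect_equal(back$seed, 9)
})
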