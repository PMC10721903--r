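# Recruitment filtering, KPKG arithmetic, profiles, rankings.

mk_hit <- function(qseqid, sseqid = "v1", pident = 99, qstart = 1,
                   qend = 150, bitscore = 290, qlen = 150, length = NULL) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length %||% (qend - qstart + 1), mismatch = 0,
             gapopen = 0, qstart = qstart, qend = qend, sstart = 1,
             send = qend - qstart + 1, evalue = 1e-30, bitscore = bitscore,
             qlen = qlen, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("tier thresholds follow the dual identity/coverage scheme", {
  hits <- rbind(mk_hit("r1", pident = 96, qend = 135),  # id 96, qcov 90
                mk_hit("r2", pident = 80, qend = 90),   # id 80, qcov 60
                mk_hit("r3", pident = 60))              # id 60
  expect_identical(filter_recruits(hits, "species")$qseqid, "r1")
  expect_setequal(filter_recruits(hits, "genus")$qseqid, c("r1", "r2"))
})

test_that("best-hit dedup precedes filtering so tiers nest", {
  hits <- rbind(mk_hit("r1", sseqid = "vB", pident = 99, bitscore = 250),
                mk_hit("r1", sseqid = "vA", pident = 80, bitscore = 280),
                mk_hit("r2", sseqid = "vA", pident = 99, bitscore = 100),
                mk_hit("r2", sseqid = "vB", pident = 99, bitscore = 100))
  sp <- filter_recruits(hits, "species")
  ge <- filter_recruits(hits, "genus")
  # r1's best hit (vA, 280) fails species but passes genus
  expect_false("r1" %in% sp$qseqid)
  expect_true("r1" %in% ge$qseqid)
  # bitscore tie -> lexicographically smallest subject
  expect_identical(ge$sseqid[ge$qseqid == "r2"], "vA")
  # nesting + per-read uniqueness
  expect_true(all(paste(sp$qseqid, sp$sseqid) %in% paste(ge$qseqid, ge$sseqid)))
  expect_equal(anyDuplicated(ge$qseqid), 0)
})

test_that("compute_kpkg arithmetic, linearity and errors", {
  expect_equal(compute_kpkg(1000, 10000, 1e9), 0.1)
  expect_equal(compute_kpkg(0, 10000, 1e9), 0)
  expect_equal(compute_kpkg(2000, 10000, 1e9), 2 * compute_kpkg(1000, 10000, 1e9))
  expect_equal(compute_kpkg(1000, 10000, 2e9), compute_kpkg(1000, 10000, 1e9) / 2)
  # unit invariance: bp in, consistent normalisation out
  expect_equal(compute_kpkg(1500, 30000, 5e8), (1.5 / 30) / 0.5)
  expect_error(compute_kpkg(100, 0, 1e9), "genome")
  expect_error(compute_kpkg(100, 1e4, 0), "dataset")
  expect_error(compute_kpkg(-1, 1e4, 1e9), "recruited")
})

test_that("recruitment_profile sums retained best hits and labels kinds", {
  samples <- data.frame(sample_id = c("mg1", "mt1"),
                        kind = c("metagenome", "metatranscriptome"),
                        dataset_size_bp = c(1e9, 5e8))
  hits <- list(
    mg1 = rbind(mk_hit("r1", "vA"), mk_hit("r2", "vA"), mk_hit("r3", "vB")),
    mt1 = mk_hit("r4", "vB"))
  lens <- c(vA = 10000, vB = 20000)
  p <- recruitment_profile(hits, lens, samples, "species")
  expect_equal(nrow(p), 4) # all contig x sample combos, zeros kept
  expect_equal(p$recruited_bp[p$contig_id == "vA" & p$sample_id == "mg1"], 300)
  expect_equal(p$recruited_bp[p$contig_id == "vA" & p$sample_id == "mt1"], 0)
  expect_equal(p$kpkg[p$contig_id == "vA" & p$sample_id == "mg1"],
               compute_kpkg(300, 10000, 1e9))
  expect_identical(unique(p$measure[p$sample_id == "mt1"]), "activity")
  expect_identical(unique(p$measure[p$sample_id == "mg1"]), "abundance")
  # kpkg = 0 exactly when recruited_bp = 0
  expect_identical(p$kpkg == 0, p$recruited_bp == 0)
  expect_error(recruitment_profile(hits, c(vA = 10000), samples, "species"),
               "unknown contig")
})

test_that("profile conservation bound holds on simulated samples", {
  com <- get_tiny_com()
  vlen <- setNames(nchar(unclass(com$viruses)), names(com$viruses))
  p <- recruitment_profile(com$hits_by_sample, vlen, com$samples, "species")
  for (sid in com$samples$sample_id) {
    reads <- unique(com$hits_by_sample[[sid]]$qseqid)
    expect_lte(sum(p$recruited_bp[p$sample_id == sid]),
               length(reads) * com$params$read_length)
  }
})

test_that("top_viruses ranks by kpkg with deterministic ties", {
  prof <- data.frame(contig_id = c("vB", "vA", "vC", "vD"),
                     sample_id = "s1", kpkg = c(5, 5, 9, 1))
  t3 <- top_viruses(prof, n = 3)
  expect_identical(t3$contig_id, c("vC", "vA", "vB"))
  expect_identical(t3$rank, 1:3)
  t9 <- top_viruses(prof, n = 9)
  expect_equal(nrow(t9), 4)
  expect_error(top_viruses(prof[0, ]), "empty")
})

test_that("planted dominant viruses top their sample rankings", {
  com <- get_tiny_com()
  vlen <- setNames(nchar(unclass(com$viruses)), names(com$viruses))
  p <- recruitment_profile(com$hits_by_sample, vlen, com$samples, "species")
  top <- top_viruses(p, 3)
  for (sid in com$samples$sample_id[com$samples$kind == "metagenome"]) {
    expect_identical(top$contig_id[top$sample_id == sid & top$rank == 1],
                     com$truth$dominant$abundance)
  }
  for (sid in com$samples$sample_id[com$samples$kind == "metatranscriptome"]) {
    expect_identical(top$contig_id[top$sample_id == sid & top$rank == 1],
                     com$truth$dominant$activity)
  }
})
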