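# CRISPR detection, spacer/tRNA matching, Markov likelihood, codon usage,
# AMG detection, evidence integration.

test_that("detect_crispr recovers planted arrays with exact coordinates", {
  com <- get_tiny_com()
  arrays <- detect_crispr(com$hosts$seqs)
  for (tr in com$truth$crispr_arrays) {
    hit <- Filter(function(a) a$host_id == tr$host_id &&
                    identical(a$repeat_starts, tr$repeat_starts), arrays)
    expect_length(hit, 1)
    a <- hit[[1]]
    expect_equal(a$repeat_len, tr$repeat_len)
    expect_identical(a$spacers, tr$spacers)
    expect_equal(a$n_copies, length(tr$repeat_starts))
    expect_equal(length(a$spacers), a$n_copies - 1) # spec invariant
  }
  # both strands found: the planted set alternates orientation
  strands <- vapply(com$truth$crispr_arrays, `[[`, "", "strand")
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("detect_crispr finds nothing in random sequence", {
  set.seed(33)
  for (i in 1:5) {
    g <- seq_set(setNames(random_dna_str(50000), "rand"), "dna")
    expect_length(detect_crispr(g), 0)
  }
})

test_that("detect_crispr respects repeat/spacer length windows", {
  set.seed(17)
  mkarr <- function(rep_len, sp_len, copies = 4) {
    r <- random_dna_str(rep_len)
    paste0(paste0(vapply(seq_len(copies - 1),
                         function(i) paste0(r, random_dna_str(sp_len)), ""),
                  collapse = ""), r)
  }
  bg <- random_dna_str(4000)
  ins <- function(arr) seq_set(setNames(paste0(bg, arr, random_dna_str(500)),
                                        "h"), "dna")
  expect_gte(length(detect_crispr(ins(mkarr(28, 32)))), 1)
  expect_length(detect_crispr(ins(mkarr(28, 60))), 0)  # spacers too long
  expect_length(detect_crispr(ins(mkarr(28, 32, copies = 2))), 0) # too few
})

test_that("match_spacers honors the mismatch budget and strand", {
  set.seed(8)
  proto <- random_dna_str(32)
  virus_fwd <- seq_set(setNames(
    paste0(random_dna_str(400), proto, random_dna_str(400)), "vf"), "dna")
  virus_rc <- seq_set(setNames(
    paste0(random_dna_str(400), revcomp(proto), random_dna_str(400)), "vr"),
    "dna")
  mut <- function(s, k) { # k fixed substitutions
    v <- strsplit(s, "")[[1]]
    for (i in sample(length(v), k)) v[i] <- setdiff(c("A","C","G","T"), v[i])[1]
    paste(v, collapse = "")
  }
  virus_mm2 <- seq_set(setNames(
    paste0(random_dna_str(400), mut(proto, 2), random_dna_str(400)), "v2"),
    "dna")
  arrays <- list(list(host_id = "h1", spacers = proto))
  ev <- match_spacers(arrays, virus_fwd)
  expect_true(ev$passed[ev$virus_id == "vf"])
  expect_equal(ev$score[ev$virus_id == "vf"], 0)
  ev <- match_spacers(arrays, virus_rc)
  expect_true(ev$passed[ev$virus_id == "vr"])
  expect_match(ev$detail[ev$virus_id == "vr"], "strand=-")
  ev <- match_spacers(arrays, virus_mm2, max_mismatches = 1)
  expect_false(any(ev$passed))
  ev <- match_spacers(arrays, virus_mm2, max_mismatches = 2)
  expect_true(any(ev$passed))
})

test_that("match_spacers at zero mismatches retrieves exactly the planted links", {
  com <- get_tiny_com()
  arrays <- detect_crispr(com$hosts$seqs)
  ev <- match_spacers(arrays, com$viruses, max_mismatches = 0)
  got <- unique(ev[ev$passed, c("virus_id", "host_id")])
  planted <- unique(data.frame(
    virus_id = vapply(com$truth$crispr_arrays, `[[`, "", "virus_id"),
    host_id = vapply(com$truth$crispr_arrays, `[[`, "", "host_id")))
  expect_identical(got[order(got$virus_id), ],
                   planted[order(planted$virus_id), ],
                   ignore_attr = TRUE)
})

test_that("match_trna applies the alignment/identity/mismatch thresholds", {
  set.seed(9)
  t_seq <- random_dna_str(72)
  host_full <- seq_set(setNames(
    paste0(random_dna_str(300), t_seq, random_dna_str(300)), "hA"), "dna")
  # 59 bp fragment whose flank mismatches the rest of the tRNA at every
  # position, so the local alignment cannot profitably extend past 59 bp
  block <- chartr("ACGT", "TGCA", substr(t_seq, 60, 72))
  host_short <- seq_set(setNames(
    paste0(random_dna_str(300), substr(t_seq, 1, 59), block,
           random_dna_str(300)), "hB"), "dna")
  trnas <- seq_set(setNames(t_seq, "t1"), "dna")
  map <- c(t1 = "v1")
  ev <- match_trna(trnas, host_full, map)
  expect_true(ev$passed)       # 72 bp, 100% identity
  expect_identical(ev$virus_id, "v1")
  ev <- match_trna(trnas, host_short, map)
  expect_false(any(ev$passed)) # best alignment 59 bp < 60
  expect_error(match_trna(trnas, host_full, c(zz = "v1")), "mapping")
})

test_that("train_markov rows normalise and discriminate generator hosts", {
  com <- get_tiny_com()
  m <- train_markov(com$hosts$seqs[1], k = 8)
  expect_equal(unname(rowSums(exp(m$logp))), rep(1, 4^7), tolerance = 1e-12)
  expect_error(train_markov(c(p = "MKVLW"), k = 4), "DNA")
  expect_warning(train_markov(c(h = "ACGTACGTAC"), k = 3), "pseudocount")

  # homopolymer: P(A | A^7) -> 1
  mono <- train_markov(setNames(paste(rep("A", 5000), collapse = ""), "mono"),
                       k = 8)
  expect_gt(exp(mono$logp["AAAAAAA", "A"]), 0.99)

  # fragments score higher under their own host's model
  set.seed(3)
  models <- lapply(seq_set_names <- setNames(names(com$hosts$seqs),
                                             names(com$hosts$seqs)),
                   function(h) train_markov(com$hosts$seqs[h], k = 8))
  h1 <- names(com$hosts$seqs)[1]; h2 <- names(com$hosts$seqs)[2]
  s1 <- unclass(com$hosts$seqs)[[h1]]
  frags <- vapply(1:10, function(i) {
    st <- sample(nchar(s1) - 5000, 1); substr(s1, st, st + 4999)
  }, "")
  names(frags) <- paste0("f", 1:10)
  own <- wish_loglik(models[[h1]], frags)$score
  cross <- wish_loglik(models[[h2]], frags)$score
  expect_true(all(own > cross))
})

test_that("wish_loglik closed form and pass window", {
  u <- uniform_markov(k = 8)
  set.seed(4)
  v <- setNames(random_dna_str(5000), "v")
  ll <- wish_loglik(u, v)
  expect_equal(ll$score, log(0.25), tolerance = 1e-12)
  expect_false(ll$passed) # -1.386 outside [-1.30, -1.20]
  # window edges are inclusive: a window pinned at the realised score passes
  expect_true(wish_loglik(u, v, window = rep(ll$score, 2))$passed)
})

test_that("codon_usage frequencies and distances", {
  cu <- codon_usage("ATGATG")
  expect_equal(unname(cu["ATG"]), 1)
  expect_equal(sum(cu), 1)
  expect_warning(cu2 <- codon_usage(c("ATGATGA")), "dropped")
  expect_equal(unname(cu2["ATG"]), 1)
  expect_equal(codon_distance(cu, cu), 0)
  set.seed(5)
  r1 <- codon_usage(random_dna_str(3000))
  expect_equal(sum(r1), 1)
  expect_error(codon_usage(character(0)), "empty")
  expect_error(suppressWarnings(codon_usage("AT")), "complete codons")
})

test_that("detect_amg applies the e-value/identity/coverage criteria", {
  mk <- function(qseqid, sseqid, pident, qcov, evalue, qlen = 200) {
    qend <- round(qlen * qcov / 100)
    data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
               length = qend, mismatch = 0, gapopen = 0, qstart = 1,
               qend = qend, sstart = 1, send = qend, evalue = evalue,
               bitscore = 100, qlen = qlen)
  }
  hits <- rbind(mk("vp1", "hg1", 60, 80, 1e-10),  # AMG
                mk("vp2", "hg2", 40, 90, 1e-10),  # identity fail
                mk("vp3", "hg3", 60, 30, 1e-10),  # coverage fail
                mk("vp4", "hg4", 60, 90, 5e-5))   # e-value not better than 5e-5
  pv <- setNames(paste0("v", 1:4), paste0("vp", 1:4))
  ph <- setNames(paste0("h", 1:4), paste0("hg", 1:4))
  res <- detect_amg(hits, pv, ph)
  expect_identical(res$amgs$viral_orf, "vp1")
  expect_identical(res$amgs$host_id, "h1")
  expect_equal(sum(res$evidence$passed), 1)
  expect_error(detect_amg(hits, pv[-1], ph), "unmapped viral")
})

test_that("planted AMGs at 10% divergence are fully recovered, no false pairs", {
  com <- get_tiny_com()
  res <- detect_amg(com$hits_amg, com$protein_virus, com$hosts$protein_host)
  found <- paste(res$amgs$viral_orf, res$amgs$host_gene)
  planted <- paste(com$truth$amg_pairs$viral_orf, com$truth$amg_pairs$host_gene)
  expect_setequal(found, planted)
})

test_that("zero AMG divergence gives identity 100", {
  p <- tiny_params(seed = 77, amg_aa_divergence = 0)
  withr::with_options(list(icevir.quiet = TRUE), {
    hosts <- generate_hosts(p)
    vir <- generate_viruses(p, hosts)
  })
  expect_true(all(vir$truth$amg_pairs$identity == 100))
  res <- detect_amg(vir$hits_amg, vir$protein_virus, hosts$protein_host)
  expect_true(all(res$amgs$pident == 100))
})

test_that("integrate_evidence follows the strong/supporting hierarchy", {
  ev <- function(v, h, etype, passed = TRUE) {
    data.frame(virus_id = v, host_id = h, etype = etype, score = 1,
               passed = passed, detail = "")
  }
  # crispr only -> strong
  a <- integrate_evidence(ev("v1", "h1", "crispr"))
  expect_identical(a$tier, "strong")
  expect_identical(a$host_id, "h1")
  # binning only -> unassigned
  a <- integrate_evidence(ev("v1", "h1", "binning"))
  expect_identical(a$tier, "unassigned")
  expect_true(is.na(a$host_id))
  # wish + codon -> supporting
  a <- integrate_evidence(rbind(ev("v1", "h1", "wish"),
                                ev("v1", "h1", "codon")))
  expect_identical(a$tier, "supporting")
  # one supporting item never assigns
  a <- integrate_evidence(ev("v1", "h1", "wish"))
  expect_identical(a$tier, "unassigned")
  # strong beats any number of supporting items on another host
  a <- integrate_evidence(rbind(ev("v1", "h1", "trna"),
                                ev("v1", "h2", "wish"),
                                ev("v1", "h2", "codon"),
                                ev("v1", "h2", "binning")))
  expect_identical(a$host_id, "h1")
  expect_identical(a$tier, "strong")
  # competing strong hosts: most strong wins; exact tie -> ambiguous
  a <- integrate_evidence(rbind(ev("v1", "h1", "crispr"),
                                ev("v1", "h1", "amg"),
                                ev("v1", "h2", "trna")))
  expect_identical(a$host_id, "h1")
  a <- integrate_evidence(rbind(ev("v1", "h1", "crispr"),
                                ev("v1", "h2", "trna")))
  expect_identical(a$tier, "unassigned")
  expect_true(a$ambiguous)
  # failed evidence never counts
  a <- integrate_evidence(ev("v1", "h1", "crispr", passed = FALSE))
  expect_identical(a$tier, "unassigned")
})

test_that("integration is invariant to evidence row order", {
  com <- get_tiny_com()
  arrays <- detect_crispr(com$hosts$seqs)
  ev <- rbind(match_spacers(arrays, com$viruses),
              match_trna(com$trnas, com$hosts$seqs, com$trna_virus),
              detect_amg(com$hits_amg, com$protein_virus,
                         com$hosts$protein_host)$evidence)
  a1 <- integrate_evidence(ev, viruses = names(com$viruses))
  set.seed(2)
  a2 <- integrate_evidence(ev[sample(nrow(ev)), ],
                           viruses = names(com$viruses))
  expect_identical(a1[order(a1$virus_id), ], a2[order(a2$virus_id), ],
                   ignore_attr = TRUE)
})
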