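# Protein clusters, MCL, hypergeometric network, intergenomic similarity,
# taxa demarcation.

test_that("filter_protein_edges applies thresholds and merges reciprocals", {
  hits <- data.frame(
    qseqid = c("a", "a", "b", "a", "a"),
    sseqid = c("b", "b", "a", "a", "c"),
    pident = 50, length = 100, mismatch = 0, gapopen = 0,
    qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = c(1e-6, 1e-4, 1e-8, 1e-9, 1e-6),
    bitscore = c(55, 200, 70, 300, 40))
  e <- filter_protein_edges(hits)
  # self-hit dropped, 1e-4 dropped, bitscore 40 dropped; reciprocal merged
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 70) # max of 55 and 70
  expect_identical(c(e$from, e$to), c("a", "b"))
})

test_that("mcl recovers obvious structure", {
  tri2 <- data.frame(
    from = c("a", "b", "c", "x", "y", "z"),
    to = c("b", "c", "a", "y", "z", "x"),
    weight = 1)
  res <- mcl(tri2, inflation = 2)
  expect_true(res$converged)
  expect_equal(length(res$clusters), 2)
  expect_identical(canonical_clusters(res$clusters),
                   list(c("a", "b", "c"), c("x", "y", "z")))

  res <- mcl(data.frame(from = "a", to = "b", weight = 1))
  expect_identical(res$clusters, list(c("a", "b")))

  # isolated nodes become their own clusters; partition property holds
  res <- mcl(tri2, nodes = c("solo", "a", "b", "c", "x", "y", "z"))
  memb <- res$membership
  expect_setequal(names(memb), c("solo", "a", "b", "c", "x", "y", "z"))
  expect_equal(anyDuplicated(names(memb)), 0)
  expect_error(mcl(tri2, inflation = 1), "inflation")
  expect_error(mcl(data.frame(from = "a", to = "b", weight = -1)),
               "negative")
})

test_that("mcl output is a partition on random graphs", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(2:15, 1)
    adj <- random_graph(n, weighted = i %% 2 == 0)
    res <- mcl(adj)
    memb <- res$membership
    expect_setequal(names(memb), rownames(adj))
    expect_equal(sum(lengths(res$clusters)), n)
  }
})

test_that("hypergeometric similarity: closed form and monotonicity", {
  # C(1,1)*C(9,0)/C(10,1) = 0.1 -> score exactly 1
  h <- hypergeometric_similarity(1, 1, 1, 10, n_pairs = 1)
  expect_equal(h$pvalue, 0.1)
  expect_equal(h$score, 1.0)
  # shared 0 -> pvalue 1, score -log10(n_pairs) <= 0
  h0 <- hypergeometric_similarity(5, 5, 0, 20, n_pairs = 45)
  expect_equal(h0$pvalue, 1)
  expect_equal(h0$score, -log10(45))
  expect_lte(h0$score, 0)
  # monotone non-increasing pvalue in shared at fixed margins
  p <- hypergeometric_similarity(rep(6, 5), rep(8, 5), 0:4, 25)$pvalue
  expect_true(all(diff(p) <= 1e-15))
  expect_error(hypergeometric_similarity(1, 1, 1, 0), "universe")
  expect_error(hypergeometric_similarity(3, 2, 3, 10), "shared")
})

test_that("build_vcs: thresholds, singletons, degenerate limits", {
  com <- get_tiny_com()
  pcs <- protein_clusters(com$hits_protein, com$protein_virus)
  # every mapped protein in exactly one PC
  expect_setequal(pcs$protein_id, names(com$protein_virus))
  expect_equal(anyDuplicated(pcs$protein_id), 0)

  scores <- genome_pair_scores(pcs)
  v <- build_vcs(scores)
  expect_true(all(table(v$vcs$vc_id) >= 2))
  expect_setequal(c(v$vcs$genome_id, v$singletons), attr(scores, "genomes"))

  # infinite threshold -> everything singleton
  v_inf <- build_vcs(scores, score_threshold = Inf)
  expect_equal(nrow(v_inf$vcs), 0)
  expect_equal(singleton_fraction(v_inf$vcs, attr(scores, "genomes")), 1)

  # -Inf threshold equals mcl on the full score graph
  v_all <- build_vcs(scores, score_threshold = -Inf)
  full <- mcl(data.frame(from = scores$genome_a, to = scores$genome_b,
                         weight = pmax(scores$score, .Machine$double.eps)),
              nodes = attr(scores, "genomes"))
  expect_identical(
    canonical_clusters(c(unname(split(v_all$vcs$genome_id, v_all$vcs$vc_id)),
                         as.list(v_all$singletons))),
    canonical_clusters(full$clusters))
})

test_that("singleton_fraction arithmetic", {
  vcs <- data.frame(vc_id = c("VC1", "VC1", "VC2", "VC2"),
                    genome_id = c("a", "b", "c", "d"))
  expect_equal(singleton_fraction(vcs, c(letters[1:4], "e", "f", "g", "h",
                                         "i", "j")), 0.6)
  expect_equal(singleton_fraction(vcs, letters[1:4]), 0)
  expect_error(singleton_fraction(vcs, character(0)), "zero genomes")
})

test_that("jaccard_vc set arithmetic", {
  expect_equal(jaccard_vc(c("p1", "p2"), c("p1", "p2")), 1)
  expect_equal(jaccard_vc(c("p1"), c("p2")), 0)
  expect_equal(jaccard_vc(c("p1", "p2"), c("p2", "p3")), 1 / 3)
  expect_error(jaccard_vc(character(0), character(0)), "empty")
})

test_that("intergenomic_similarity: identity weighting and overlap merging", {
  full <- data.frame(qstart = 1, qend = 10000, pident = 100)
  expect_equal(intergenomic_similarity(full, 10000, 10000), 100)
  expect_equal(intergenomic_similarity(full[0, ], 10000, 10000), 0)
  half <- data.frame(qstart = 1, qend = 5000, pident = 100)
  expect_equal(intergenomic_similarity(half, 10000, 10000), 50)
  # overlapping intervals counted once, higher identity wins on the overlap
  ov <- data.frame(qstart = c(1, 4001), qend = c(6000, 10000),
                   pident = c(100, 80))
  # 6000 bases at 100% + 4000 at 80% = (6000 + 3200)/10000
  expect_equal(intergenomic_similarity(ov, 10000, 10000), 92)
  # asymmetric lengths use the mean as denominator
  expect_equal(intergenomic_similarity(half, 10000, 30000), 25)
})

test_that("demarcate_taxa: cutoffs, nesting and refinement", {
  sim <- matrix(c(100, 96, 10,
                  96, 100, 10,
                  10, 10, 100), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t1 <- demarcate_taxa(sim)
  expect_equal(t1$species[["a"]], t1$species[["b"]]) # 96 >= 95
  expect_equal(t1$genus[["a"]], t1$genus[["b"]])
  expect_false(t1$genus[["a"]] == t1$genus[["c"]])

  sim["a", "b"] <- sim["b", "a"] <- 80 # same genus, different species
  t2 <- demarcate_taxa(sim)
  expect_false(t2$species[["a"]] == t2$species[["b"]])
  expect_equal(t2$genus[["a"]], t2$genus[["b"]])

  bad <- sim; bad["a", "b"] <- 50
  expect_error(demarcate_taxa(bad), "symmetric")

  # species always refines genus; raising a cutoff never merges
  set.seed(21)
  for (i in 1:15) {
    n <- sample(3:10, 1)
    m <- matrix(runif(n * n, 0, 100), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 100
    dimnames(m) <- list(paste0("g", 1:n), paste0("g", 1:n))
    cuts <- sort(runif(2, 10, 95))
    tt <- demarcate_taxa(m, species_cutoff = cuts[2], genus_cutoff = cuts[1])
    # each species cluster maps into exactly one genus cluster
    expect_true(all(tapply(tt$genus, tt$species,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("planted genus/species structure is recovered end to end", {
  com <- get_tiny_com()
  vlen <- setNames(nchar(unclass(com$viruses)), names(com$viruses))
  sim <- similarity_matrix(com$pair_hits_nt, vlen)
  tt <- demarcate_taxa(sim)
  genus_part <- split(names(tt$genus), tt$genus)
  planted <- split(names(com$truth$genus_of), com$truth$genus_of)
  expect_identical(canonical_clusters(unname(genus_part)),
                   canonical_clusters(unname(planted)))
  sp_part <- split(names(tt$species), tt$species)
  planted_sp <- split(names(com$truth$species_of), com$truth$species_of)
  expect_identical(canonical_clusters(unname(sp_part)),
                   canonical_clusters(unname(planted_sp)))
})
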