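# Synthetic community generator with planted ground truth.
#
# Emulates the inputs the pipeline consumes in a real study -- host
# MAGs/SAGs, candidate viral contigs with a screening table, protein sets,
# BLAST-style hit tables, per-sample read recruitment -- with every
# downstream answer planted and recorded in a truth object: virus-host
# pairs (CRISPR / tRNA / AMG), lifestyles, genus/species labels, per-sample
# expected KPKG, CRISPR array coordinates.
#
# Hosts are order-2 Markov sequences whose per-context G/C and A/T splits
# are Beta-perturbed per host (compositional signal for k-mer host
# prediction) while each context row keeps the host's exact GC content, so
# realised GC tracks the requested value to binomial precision. Viral
# sequences are drawn from a sharpened (power-transformed) copy of their
# composition host's transition table, with the exponent solved so the
# expected per-nucleotide log-likelihood under the trained k = 8 model sits
# at `wish_target` -- the midpoint of the WisH-style pass window.

CODONS_FOR_AA <- local({
  gc_tbl <- Biostrings::GENETIC_CODE
  split(names(gc_tbl), gc_tbl)[setdiff(unique(gc_tbl), "*")]
})

# rough marine-proteome-like residue frequencies
AA_FREQ <- c(A = 0.085, R = 0.05, N = 0.042, D = 0.055, C = 0.012,
             Q = 0.038, E = 0.062, G = 0.072, H = 0.02, I = 0.065,
             L = 0.098, K = 0.06, M = 0.024, F = 0.042, P = 0.04,
             S = 0.062, T = 0.054, W = 0.011, Y = 0.032, V = 0.076)

#' Parameters of the synthetic community
#'
#' Defaults state the world the pipeline was designed for: 20 hosts and 200
#' viruses, a dsDNA-dominated class mix, mean dsDNA contig size 19.4 kb and
#' ssDNA/RNA ~4 kb, a 3% temperate fraction, 56% gene-sharing singletons,
#' and 60 planted strong-evidence virus-host pairs (20 CRISPR + 20 tRNA +
#' 20 AMG) with 10% amino-acid AMG divergence.
#'
#' @param seed mandatory integer seed; every generator draw derives from it
#' @param ... overrides of the defaults listed in the source
#' @return validated parameter list of class `synth_params`
#' @export
synth_params <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  p <- list(
    seed = as.integer(seed),
    n_hosts = 20L, n_viruses = 200L,
    host_length = 100000L, gc = 0.42, gc_jitter = 0.01,
    comp_beta_conc = 6,
    class_props = c(dsDNA = 0.59, ssDNA = 0.35, NCLDV = 0.04,
                    Lavidaviridae = 0.013, RNA = 0.007),
    temperate_fraction = 0.03,
    singleton_fraction = 0.56,
    genus_size_range = c(2L, 4L), species_pair_rate = 0.3,
    n_crispr_pairs = 20L, n_trna_pairs = 20L, n_amg_pairs = 20L,
    n_binning_only = 6L,
    amg_aa_divergence = 0.10,
    spacer_len = 32L, repeat_len = 28L, crispr_copies = c(3L, 6L),
    trna_len = 75L,
    genes_per_host = 40L, host_protein_len = 250L,
    proteins_per_virus = c(8L, 15L), viral_protein_len = 200L,
    shared_families = 10L, unique_proteins = 3L,
    family_divergence = 0.15,
    read_length = 150L, reads_per_sample = 20000L, error_rate = 0.01,
    n_junk_reads = 300L, n_mid_reads = 300L, secondary_hit_rate = 0.1,
    dominant_boost = 50,
    wish_k = 8L, wish_target = -1.25)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(abs(sum(p$class_props) - 1) < 1e-6,
            p$temperate_fraction >= 0, p$temperate_fraction <= 1,
            p$singleton_fraction >= 0, p$singleton_fraction <= 1,
            p$error_rate >= 0, p$error_rate <= 1,
            p$amg_aa_divergence >= 0, p$amg_aa_divergence <= 1)
  if (p$n_amg_pairs > p$n_hosts * p$genes_per_host) {
    stop("more AMG pairs requested than host genes available")
  }
  structure(p, class = "synth_params")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(names(AA_FREQ), n, replace = TRUE, prob = AA_FREQ),
        collapse = "")
}

mutate_protein <- function(aa, rate) {
  v <- strsplit(aa, "")[[1]]
  n_mut <- round(rate * length(v))
  if (n_mut == 0) return(aa)
  pos <- sample(length(v), n_mut)
  for (i in pos) v[i] <- sample(setdiff(names(AA_FREQ), v[i]), 1)
  paste(v, collapse = "")
}

protein_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- min(length(va), length(vb))
  100 * mean(va[1:n] == vb[1:n])
}

backtranslate <- function(aa, bias) {
  v <- strsplit(aa, "")[[1]]
  out <- character(length(v))
  for (a in unique(v)) {
    idx <- which(v == a)
    cods <- CODONS_FOR_AA[[a]]
    out[idx] <- sample(cods, length(idx), replace = TRUE, prob = bias[[a]])
  }
  paste(out, collapse = "")
}

# order-2 transition table: per-context G/C and A/T splits Beta-perturbed,
# GC content of every row pinned at gc
host_transition <- function(gc, conc) {
  s <- rbeta(16, conc, conc) # G share of GC
  u <- rbeta(16, conc, conc) # A share of AT
  q <- cbind(A = (1 - gc) * u, C = gc * (1 - s), G = gc * s,
             T = (1 - gc) * (1 - u))
  b <- c("A", "C", "G", "T")
  rownames(q) <- paste0(rep(b, each = 4), rep(b, times = 4)) # index 4*b1+b2
  q
}

pair_init <- function(gc) {
  p1 <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rep(p1, each = 4) * rep(p1, times = 4) # index 4*b1 + b2
}

markov_sequence <- function(n, trans, gc) {
  .markov_gen_cpp(as.integer(n), trans, pair_init(gc))
}

sharpen_rows <- function(q, beta) {
  qs <- q^beta
  qs / rowSums(qs)
}

# expected per-nucleotide log-likelihood of an order-2 source `q` scored by
# a trained k-mer model (logp: 4^(k-1) x 4, lexicographic contexts)
expected_wish <- function(q, logp, k) {
  stopifnot(nrow(logp) == 4^(k - 1))
  # stationary over base pairs of the order-2 chain
  P <- matrix(0, 16, 16)
  for (st in 1:16) {
    b2 <- (st - 1) %% 4
    for (b3 in 0:3) P[st, 4 * b2 + b3 + 1] <- q[st, b3 + 1]
  }
  ev <- Re(eigen(t(P))$vectors[, 1])
  pi2 <- ev / sum(ev)
  # propagate to a distribution over (k-1)-mer contexts
  v <- pi2
  t_len <- 2
  while (t_len < k - 1) {
    idx <- 0:(4^t_len - 1)
    mult <- as.vector(t(q[(idx %% 16) + 1, , drop = FALSE]))
    v <- rep(v, each = 4) * mult
    t_len <- t_len + 1
  }
  idx <- 0:(4^(k - 1) - 1)
  qrows <- q[(idx %% 16) + 1, , drop = FALSE]
  sum(v * qrows * logp)
}

solve_wish_beta <- function(q, logp, k, target) {
  f <- function(b) expected_wish(sharpen_rows(q, b), logp, k) - target
  lo <- f(1)
  if (lo >= 0) return(1)
  hi <- f(12)
  if (hi <= 0) return(12)
  uniroot(f, c(1, 12), tol = 1e-4)$root
}

#' Generate host genomes, gene sets and composition models
#'
#' @param params a [synth_params()] object
#' @return list with `seqs` ([seq_set()]), `trans` (per-host order-2
#'   transition tables), `gc` (realised targets), `codon_bias`, `proteins`
#'   and `cds` (named lists per host), `protein_host` (protein id -> host)
#' @export
generate_hosts <- function(params) {
  set.seed(params$seed + 11L)
  ids <- sprintf("h%02d", seq_len(params$n_hosts))
  seqs <- character(0)
  trans <- list(); gcs <- numeric(0); bias <- list()
  proteins <- list(); cds <- list()
  for (hid in ids) {
    gc_i <- params$gc + runif(1, -params$gc_jitter, params$gc_jitter)
    q <- host_transition(gc_i, params$comp_beta_conc)
    seqs[hid] <- markov_sequence(params$host_length, q, gc_i)
    trans[[hid]] <- q
    gcs[hid] <- gc_i
    bias[[hid]] <- lapply(CODONS_FOR_AA, function(cods) {
      w <- rgamma(length(cods), shape = 2)
      w / sum(w)
    })
    plen <- pmax(60L, rpois(params$genes_per_host, params$host_protein_len))
    prot <- vapply(plen, random_protein, "")
    names(prot) <- sprintf("%s_g%03d", hid, seq_along(prot))
    proteins[[hid]] <- prot
    cds[[hid]] <- vapply(prot, backtranslate, "", bias = bias[[hid]])
  }
  protein_host <- setNames(rep(ids, each = params$genes_per_host),
                           unlist(lapply(proteins, names)))
  list(seqs = seq_set(seqs, "dna"), trans = trans, gc = gcs,
       codon_bias = bias, proteins = proteins, cds = cds,
       protein_host = protein_host)
}

# reserve a random interval of length len in a host, avoiding previous
# reservations; returns start or NA
reserve_interval <- function(reserved, L, len, tries = 200) {
  for (i in seq_len(tries)) {
    start <- sample(L - len - 200, 1) + 100
    ok <- !any(start <= reserved$end + 5 & start + len - 1 >= reserved$start - 5)
    if (nrow(reserved) == 0 || ok) return(start)
  }
  NA_integer_
}

splice_in <- function(genome, start, insert) {
  substr(genome, start, start + nchar(insert) - 1) <- insert
  genome
}

#' Generate the viral side of the community (and edit hosts in place)
#'
#' Builds core viral contigs (class, genus/species structure, lifestyle,
#' composition host), plants strong-evidence features (CRISPR
#' spacer-protospacers into host genomes, shared tRNAs, AMG orthologs),
#' emits the screening table including decoy contigs engineered to fail each
#' triage rule, the protein sets and emulated hit tables, and records
#' everything in the truth object.
#'
#' @param params [synth_params()]
#' @param hosts output of [generate_hosts()]
#' @return list: `viruses` (core, [seq_set()]), `decoy_seqs`, `screen`,
#'   `proteins` (viral [seq_set()]), `protein_virus`, `viral_cds`, `trnas`,
#'   `trna_virus`, `hits_protein`, `hits_amg`, `pair_hits_nt`, `bins`,
#'   `bin_host`, `annotations`, `hosts` (with planted arrays/tRNAs spliced
#'   in), `truth`
#' @export
generate_viruses <- function(params, hosts) {
  set.seed(params$seed + 23L)
  n <- params$n_viruses
  vids <- sprintf("v%03d", seq_len(n))
  host_ids <- names(hosts$seqs)

  ## genus / species structure -------------------------------------------
  shuffled <- sample(vids)
  n_single <- round(params$singleton_fraction * n)
  singles <- shuffled[seq_len(n_single)]
  rest <- shuffled[-seq_len(n_single)]
  genus_of <- setNames(character(n), vids)
  genus_sizes <- integer(0)
  while (sum(genus_sizes) < length(rest)) {
    left <- length(rest) - sum(genus_sizes)
    sz <- sample(seq(params$genus_size_range[1], params$genus_size_range[2]), 1)
    if (left - sz == 1) sz <- sz + 1 # never strand a size-1 remainder
    genus_sizes <- c(genus_sizes, min(sz, left))
  }
  gidx <- 0L
  genera <- list()
  pos <- 1L
  for (sz in genus_sizes) {
    gidx <- gidx + 1L
    members <- rest[pos:(pos + sz - 1)]
    genera[[sprintf("G%03d", gidx)]] <- members
    genus_of[members] <- sprintf("G%03d", gidx)
    pos <- pos + sz
  }
  for (v in singles) {
    gidx <- gidx + 1L
    genus_of[v] <- sprintf("G%03d", gidx)
  }
  species_of <- setNames(paste0("S_", vids), vids)

  ## class and length per genus ------------------------------------------
  class_of <- setNames(character(n), vids)
  len_of <- setNames(integer(n), vids)
  draw_len <- function(cl) {
    base <- switch(cl,
      dsDNA = , NCLDV = , Lavidaviridae = 10000 + rgamma(1, 2, scale = 4700),
      ssDNA = 2500 + rgamma(1, 2, scale = 750),
      RNA = 1500 + rgamma(1, 2, scale = 1250))
    as.integer(round(base))
  }
  for (g in unique(genus_of)) {
    members <- vids[genus_of == g]
    cl <- sample(names(params$class_props), 1, prob = params$class_props)
    class_of[members] <- cl
    templ <- draw_len(cl)
    len_of[members] <- as.integer(round(templ * (1 + runif(length(members),
                                                           -0.05, 0.05))))
    if (length(members) >= 2 && runif(1) < params$species_pair_rate) {
      sp <- members[1:2]
      len_of[sp[2]] <- as.integer(round(len_of[sp[1]] *
                                          (1 + runif(1, -0.005, 0.005))))
      species_of[sp] <- paste0("S_", sp[1])
    }
  }
  # core contigs are planted triage passes: keep jittered lengths above the
  # class cutoff (decoys carry the planted length failures)
  len_of <- pmax(len_of, length_cutoff(class_of) + 50L)

  ## strong-evidence pair assignment --------------------------------------
  n_pairs <- params$n_crispr_pairs + params$n_trna_pairs + params$n_amg_pairs
  if (n_pairs > n) stop("more evidence pairs requested than viruses")
  pair_vs <- sample(vids, n_pairs)
  pair_type <- setNames(rep(c("crispr", "trna", "amg"),
                            c(params$n_crispr_pairs, params$n_trna_pairs,
                              params$n_amg_pairs)), pair_vs)
  pair_host <- setNames(rep(sample(host_ids),
                            length.out = n_pairs)[seq_len(n_pairs)], pair_vs)
  comp_host <- setNames(sample(host_ids, n, replace = TRUE), vids)
  comp_host[pair_vs] <- pair_host

  ## sharpened composition models and sequences ---------------------------
  iv_log("training host k-mer models and solving sharpening exponents")
  models <- lapply(host_ids, function(h) {
    train_markov(hosts$seqs[h], k = params$wish_k)
  })
  names(models) <- host_ids
  beta_h <- vapply(host_ids, function(h) {
    solve_wish_beta(hosts$trans[[h]], models[[h]]$logp, params$wish_k,
                    params$wish_target)
  }, numeric(1))
  vseqs <- setNames(character(n), vids)
  for (v in vids) {
    h <- comp_host[v]
    q <- sharpen_rows(hosts$trans[[h]], beta_h[h])
    vseqs[v] <- markov_sequence(len_of[v], q, hosts$gc[h])
  }

  ## lifestyle -------------------------------------------------------------
  temperate <- rbinom(n, 1, params$temperate_fraction) == 1
  names(temperate) <- vids
  if (!any(temperate)) temperate[1] <- TRUE # guarantee the provirus case
  temp_ids <- vids[temperate]
  provirus <- setNames(rep(FALSE, n), vids)
  integrase <- setNames(rep(FALSE, n), vids)
  provirus[temp_ids[seq_along(temp_ids) %% 2 == 1]] <- TRUE
  integrase[temp_ids[seq_along(temp_ids) %% 2 == 0]] <- TRUE
  relax_virus <- temp_ids[provirus[temp_ids]][1] # ratio rule waived for it

  ## tRNA planting ---------------------------------------------------------
  host_seqs <- unclass(hosts$seqs)
  reserved <- lapply(host_ids, function(h) {
    data.frame(start = integer(0), end = integer(0))
  })
  names(reserved) <- host_ids
  trnas <- character(0); trna_virus <- character(0)
  trna_truth <- list()
  for (v in pair_vs[pair_type[pair_vs] == "trna"]) {
    h <- pair_host[v]
    t_seq <- random_dna(params$trna_len)
    vpos <- sample(len_of[v] - params$trna_len, 1)
    vseqs[v] <- splice_in(vseqs[v], vpos, t_seq)
    hpos <- reserve_interval(reserved[[h]], params$host_length,
                             params$trna_len)
    host_seqs[h] <- splice_in(host_seqs[h], hpos, t_seq)
    reserved[[h]] <- rbind(reserved[[h]],
                           data.frame(start = hpos,
                                      end = hpos + params$trna_len - 1))
    tid <- paste0("trna_", v)
    trnas[tid] <- t_seq
    trna_virus[tid] <- v
    trna_truth[[tid]] <- list(trna_id = tid, virus_id = v, host_id = h,
                              seq = t_seq)
  }

  ## CRISPR planting --------------------------------------------------------
  crispr_truth <- list()
  planted_spacers <- list()
  ci <- 0L
  for (v in pair_vs[pair_type[pair_vs] == "crispr"]) {
    ci <- ci + 1L
    h <- pair_host[v]
    copies <- sample(params$crispr_copies[1]:params$crispr_copies[2], 1)
    rep_seq <- random_dna(params$repeat_len)
    n_sp <- copies - 1L
    proto <- sample_protospacer(vseqs[v], params$spacer_len)
    spacers <- vapply(seq_len(n_sp), function(i) random_dna(params$spacer_len), "")
    proto_slot <- sample(n_sp, 1)
    spacers[proto_slot] <- proto
    array_str <- paste0(paste0(rep_seq, spacers, collapse = ""), rep_seq)
    strand <- if (ci %% 2 == 0) "-" else "+"
    ins <- if (strand == "-") revcomp(array_str) else array_str
    hpos <- reserve_interval(reserved[[h]], params$host_length, nchar(ins))
    host_seqs[h] <- splice_in(host_seqs[h], hpos, ins)
    reserved[[h]] <- rbind(reserved[[h]],
                           data.frame(start = hpos,
                                      end = hpos + nchar(ins) - 1))
    # forward-orientation geometry of the planted array
    period <- params$repeat_len + params$spacer_len
    fw_starts <- hpos + period * (0:(copies - 1))
    host_seqs[h] <- break_flank_unanimity(host_seqs[h], fw_starts,
                                          params$repeat_len)
    fw_sp_starts <- fw_starts[-copies] + params$repeat_len
    fw_spacers <- substring(host_seqs[h], fw_sp_starts,
                            fw_sp_starts + params$spacer_len - 1)
    crispr_truth[[length(crispr_truth) + 1L]] <- list(
      host_id = h, virus_id = v, strand = strand,
      repeat_starts = fw_starts, repeat_len = params$repeat_len,
      spacers = fw_spacers,
      protospacer = proto)
    planted_spacers[[h]] <- c(planted_spacers[[h]],
                              list(list(spacer = proto, virus_id = v)))
  }

  ## proteins, families, AMGs ----------------------------------------------
  vir_prot <- list(); viral_cds <- list()
  amg_rows <- list()
  fam_of_genus <- list()
  host_gene_pool <- unlist(lapply(hosts$proteins, identity))
  names(host_gene_pool) <- unlist(lapply(hosts$proteins, names))
  amg_host_genes <- character(0)
  for (v in vids) {
    g <- genus_of[v]
    members <- vids[genus_of == g]
    shared <- character(0)
    if (length(members) >= 2) {
      if (is.null(fam_of_genus[[g]])) {
        fam_of_genus[[g]] <- vapply(seq_len(params$shared_families),
                                    function(i) random_protein(params$viral_protein_len),
                                    "")
      }
      shared <- vapply(fam_of_genus[[g]], mutate_protein, "",
                       rate = params$family_divergence)
      n_uni <- params$unique_proteins
    } else {
      n_uni <- sample(params$proteins_per_virus[1]:params$proteins_per_virus[2], 1)
    }
    uni <- vapply(seq_len(n_uni),
                  function(i) random_protein(round(params$viral_protein_len *
                                                     runif(1, 0.7, 1.3))), "")
    prot <- c(shared, uni)
    if (!is.na(pair_type[v]) && pair_type[v] == "amg") {
      h <- pair_host[v]
      gene <- sample(names(hosts$proteins[[h]])[
        !names(hosts$proteins[[h]]) %in% amg_host_genes], 1)
      amg_host_genes <- c(amg_host_genes, gene)
      amg_prot <- mutate_protein(hosts$proteins[[h]][[gene]],
                                 params$amg_aa_divergence)
      prot <- c(prot, amg_prot)
      amg_rows[[length(amg_rows) + 1L]] <- data.frame(
        viral_orf = sprintf("%s_p%02d", v, length(prot)),
        host_gene = gene, virus_id = v, host_id = h,
        identity = protein_identity(amg_prot, hosts$proteins[[h]][[gene]]),
        stringsAsFactors = FALSE)
    }
    names(prot) <- sprintf("%s_p%02d", v, seq_along(prot))
    vir_prot[[v]] <- prot
    viral_cds[[v]] <- vapply(prot, backtranslate, "",
                             bias = hosts$codon_bias[[comp_host[v]]])
  }
  protein_virus <- setNames(rep(vids, lengths(vir_prot)),
                            unlist(lapply(vir_prot, names)))
  amg_truth <- if (length(amg_rows) > 0) do.call(rbind, amg_rows) else
    data.frame(viral_orf = character(0), host_gene = character(0),
               virus_id = character(0), host_id = character(0),
               identity = numeric(0))

  ## screening table (core + decoys) ---------------------------------------
  n_prot_of <- lengths(vir_prot)
  hallmark <- 1L + rpois(n, 1)
  host_genes <- rbinom(n, 2, 0.3)
  screen_core <- data.frame(
    contig_id = vids,
    length = as.integer(nchar(vseqs[vids])),
    viral_class = unname(class_of[vids]),
    hallmark_count = hallmark,
    viral_gene_count = unname(n_prot_of[vids]),
    host_gene_count = pmin(host_genes, unname(n_prot_of[vids]) - 1L),
    is_provirus = unname(provirus[vids]),
    viral_origin_score = round(runif(n, 0.75, 1), 3),
    stringsAsFactors = FALSE)
  ri <- which(screen_core$contig_id == relax_virus)
  screen_core$host_gene_count[ri] <- screen_core$viral_gene_count[ri] + 2L
  decoys <- data.frame(
    contig_id = sprintf("d%02d", 1:8),
    length = c(9999L, 2000L, 1400L, 12000L, 12000L, 12000L, 12000L, 12000L),
    viral_class = c("dsDNA", "ssDNA", "RNA", "dsDNA", "dsDNA", "dsDNA",
                    "dsDNA", "dsDNA"),
    hallmark_count = c(2L, 1L, 1L, 0L, 0L, 1L, 0L, 1L),
    viral_gene_count = c(5L, 3L, 3L, 4L, 5L, 4L, 2L, 5L),
    host_gene_count = c(0L, 0L, 0L, 0L, 3L, 6L, 5L, 0L),
    is_provirus = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    viral_origin_score = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.2),
    stringsAsFactors = FALSE)
  decoy_rules <- c("length_cutoff", "length_cutoff", "length_cutoff",
                   "zero_information", "no_hallmark", "host_viral_ratio",
                   "no_hallmark", "origin_screen")
  decoy_seqs <- setNames(vapply(decoys$length,
                                function(L) random_dna(L), ""),
                         decoys$contig_id)
  screen <- rbind(screen_core, decoys)
  triage_expected <- data.frame(
    contig_id = screen$contig_id,
    verdict = c(rep("accepted", n), rep("rejected", 8)),
    rule_fired = c(rep("pass", n), decoy_rules),
    stringsAsFactors = FALSE)

  ## protein all-vs-all hits ------------------------------------------------
  hp <- list()
  all_prot <- unlist(lapply(vir_prot, identity))
  names(all_prot) <- unlist(lapply(vir_prot, names))
  plen <- nchar(all_prot)
  # self-hits (to exercise the self-drop rule)
  hp[[1]] <- data.frame(
    qseqid = names(all_prot), sseqid = names(all_prot), pident = 100,
    length = plen, mismatch = 0L, gapopen = 0L, qstart = 1L, qend = plen,
    sstart = 1L, send = plen, evalue = 1e-80,
    bitscore = round(plen * 1.9), qlen = plen, stringsAsFactors = FALSE)
  for (g in names(fam_of_genus)) {
    members <- vids[genus_of == g]
    for (k in seq_len(params$shared_families)) {
      pids <- sprintf("%s_p%02d", members, k)
      for (i in seq_along(pids)) for (j in seq_along(pids)) {
        if (i == j) next
        a <- pids[i]; b <- pids[j]
        id <- protein_identity(all_prot[[a]], all_prot[[b]])
        alen <- min(plen[a], plen[b])
        hp[[length(hp) + 1L]] <- data.frame(
          qseqid = a, sseqid = b, pident = round(id, 1), length = alen,
          mismatch = round(alen * (1 - id / 100)), gapopen = 0L,
          qstart = 1L, qend = unname(plen[a]), sstart = 1L,
          send = unname(plen[b]), evalue = 1e-30,
          bitscore = round(alen * id / 100 * 1.5), qlen = unname(plen[a]),
          stringsAsFactors = FALSE)
      }
    }
  }
  # noise: fails both thresholds / one threshold
  pick <- function(k) sample(names(all_prot), k, replace = TRUE)
  mk_noise <- function(k, ev, bs) {
    a <- pick(k); b <- pick(k)
    keep <- a != b
    data.frame(qseqid = a[keep], sseqid = b[keep], pident = 30,
               length = 60L, mismatch = 40L, gapopen = 2L, qstart = 1L,
               qend = 60L, sstart = 1L, send = 60L, evalue = ev,
               bitscore = bs, qlen = unname(plen[a[keep]]),
               stringsAsFactors = FALSE)
  }
  hp[[length(hp) + 1L]] <- mk_noise(200, 1e-3, 35)
  hp[[length(hp) + 1L]] <- mk_noise(50, 1e-6, 45)
  hp[[length(hp) + 1L]] <- mk_noise(50, 1e-4, 80)
  hits_protein <- do.call(rbind, hp)
  row.names(hits_protein) <- NULL

  ## AMG hit table -----------------------------------------------------------
  ha <- list()
  if (nrow(amg_truth) > 0) {
    ql <- nchar(all_prot[amg_truth$viral_orf])
    ha[[1]] <- data.frame(
      qseqid = amg_truth$viral_orf, sseqid = amg_truth$host_gene,
      pident = round(amg_truth$identity, 1), length = ql, mismatch =
        round(ql * (1 - amg_truth$identity / 100)), gapopen = 0L,
      qstart = 1L, qend = ql, sstart = 1L, send = ql, evalue = 1e-40,
      bitscore = round(ql * 1.5), qlen = ql, stringsAsFactors = FALSE)
  }
  # decoy AMG hits: below identity / below coverage / bad e-value
  dv <- sample(names(all_prot), 3)
  dh <- sample(names(host_gene_pool), 3)
  dql <- nchar(all_prot[dv])
  ha[[length(ha) + 1L]] <- data.frame(
    qseqid = dv, sseqid = dh,
    pident = c(40, 80, 80),
    length = as.integer(round(dql * c(0.9, 0.3, 0.9))), mismatch = 10L,
    gapopen = 0L, qstart = 1L,
    qend = as.integer(round(dql * c(0.9, 0.3, 0.9))),
    sstart = 1L, send = as.integer(round(dql * c(0.9, 0.3, 0.9))),
    evalue = c(1e-20, 1e-20, 1e-3), bitscore = 60,
    qlen = dql, stringsAsFactors = FALSE)
  hits_amg <- do.call(rbind, ha)
  row.names(hits_amg) <- NULL

  ## nucleotide pair hits for intergenomic similarity ------------------------
  np <- list()
  for (g in names(fam_of_genus)) {
    members <- sort(vids[genus_of == g])
    for (i in seq_along(members)) for (j in seq_along(members)) {
      if (i >= j) next
      a <- members[i]; b <- members[j]
      mlen <- min(len_of[a], len_of[b])
      same_sp <- species_of[a] == species_of[b]
      id <- if (same_sp) 98 else 85
      if (same_sp) {
        segs <- rbind(c(1, round(0.60 * mlen)),
                      c(round(0.55 * mlen), mlen)) # overlapping on purpose
      } else {
        segs <- rbind(c(1, round(0.45 * mlen)),
                      c(round(0.50 * mlen), round(0.95 * mlen)))
      }
      np[[length(np) + 1L]] <- data.frame(
        qseqid = a, sseqid = b, pident = id,
        length = segs[, 2] - segs[, 1] + 1, mismatch = 0L, gapopen = 0L,
        qstart = segs[, 1], qend = segs[, 2], sstart = segs[, 1],
        send = segs[, 2], evalue = 0, bitscore = 2 * (segs[, 2] - segs[, 1]),
        qlen = unname(len_of[a]), stringsAsFactors = FALSE)
    }
  }
  # one cross-genus decoy alignment, far below the genus cutoff
  cross <- sample(singles, 2)
  np[[length(np) + 1L]] <- data.frame(
    qseqid = cross[1], sseqid = cross[2], pident = 70, length = 500L,
    mismatch = 150L, gapopen = 0L, qstart = 101L, qend = 600L,
    sstart = 101L, send = 600L, evalue = 1e-10, bitscore = 300,
    qlen = unname(len_of[cross[1]]), stringsAsFactors = FALSE)
  pair_hits_nt <- do.call(rbind, np)
  row.names(pair_hits_nt) <- NULL

  ## binning ------------------------------------------------------------------
  bin_host <- setNames(host_ids, paste0("bin_", host_ids))
  bin_rows <- list()
  for (v in vids[provirus[vids]]) {
    bin_rows[[length(bin_rows) + 1L]] <-
      data.frame(virus_id = v, bin_id = paste0("bin_", comp_host[v]),
                 stringsAsFactors = FALSE)
  }
  non_pair <- setdiff(vids, pair_vs)
  binning_only <- sample(setdiff(non_pair, vids[provirus[vids]]),
                         params$n_binning_only)
  for (v in binning_only) {
    bin_rows[[length(bin_rows) + 1L]] <-
      data.frame(virus_id = v, bin_id = paste0("bin_", sample(host_ids, 1)),
                 stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, bin_rows)

  ## annotations ---------------------------------------------------------------
  ann <- lapply(vids, function(v) {
    pids <- names(vir_prot[[v]])
    prod <- rep("hypothetical protein", length(pids))
    if (class_of[v] == "dsDNA" && length(pids) >= 2) {
      prod[2] <- "major capsid protein"
    }
    if (integrase[v]) prod[1] <- "phage integrase"
    amg_row <- amg_truth[amg_truth$virus_id == v, ]
    if (nrow(amg_row) > 0) {
      prod[match(amg_row$viral_orf, pids)] <- "thioredoxin-like metabolic protein"
    }
    data.frame(contig_id = v, protein_id = pids, product = prod,
               stringsAsFactors = FALSE)
  })
  annotations <- do.call(rbind, ann)

  truth <- list(
    host_of = setNames(unname(pair_host), names(pair_host)),
    pair_type = pair_type,
    comp_host = comp_host,
    amg_pairs = amg_truth,
    lifestyle = setNames(ifelse(temperate, "temperate", "lytic"), vids),
    temperate_fraction_planted = params$temperate_fraction,
    genus_of = genus_of,
    species_of = species_of,
    singleton_ids = singles,
    triage_expected = triage_expected,
    planted_spacers = planted_spacers,
    crispr_arrays = crispr_truth,
    planted_trnas = trna_truth,
    binning_only = binning_only,
    relax_virus = relax_virus,
    wish_beta = beta_h)

  hosts$seqs <- seq_set(host_seqs, "dna")
  list(viruses = seq_set(vseqs, "dna"), decoy_seqs = seq_set(decoy_seqs, "dna"),
       screen = screen, proteins = seq_set(all_prot, "protein"),
       protein_virus = protein_virus, viral_cds = viral_cds,
       trnas = if (length(trnas)) seq_set(trnas, "dna") else
         structure(character(0), moltype = "dna", class = "seq_set"),
       trna_virus = trna_virus,
       hits_protein = hits_protein, hits_amg = hits_amg,
       pair_hits_nt = pair_hits_nt, bins = bins, bin_host = bin_host,
       annotations = annotations, hosts = hosts, truth = truth,
       models = models)
}

# Protospacers are sampled from sequence-complex regions of the source
# virus: low-complexity stretches (the sharpened composition model can emit
# long AT-repeats) are not usable as planted evidence because they recur
# across genomes -- real spacer-matching pipelines dust-mask them for the
# same reason. Complexity = number of distinct trinucleotides in the window.
sample_protospacer <- function(vseq, spacer_len, min_trimers = 16,
                               tries = 200) {
  best <- NULL; best_c <- -1L
  for (i in seq_len(tries)) {
    pos <- sample(nchar(vseq) - spacer_len, 1)
    cand <- substr(vseq, pos, pos + spacer_len - 1)
    cx <- length(unique(substring(cand, 1:(spacer_len - 2), 3:spacer_len)))
    if (cx >= min_trimers) return(cand)
    if (cx > best_c) { best_c <- cx; best <- cand }
  }
  best
}

# make sure repeat-boundary columns are not unanimous across copies, so the
# planted coordinates are the unique maximal extension
break_flank_unanimity <- function(genome, starts, rep_len) {
  bases <- c("A", "C", "G", "T")
  left_idx <- starts - 1
  ch <- substring(genome, left_idx, left_idx)
  if (length(unique(ch)) == 1) {
    substr(genome, left_idx[1], left_idx[1]) <- sample(setdiff(bases, ch[1]), 1)
  }
  right_idx <- starts + rep_len
  ch <- substring(genome, right_idx, right_idx)
  if (length(unique(ch)) == 1) {
    i <- right_idx[length(right_idx)]
    substr(genome, i, i) <- sample(setdiff(bases, ch[1]), 1)
  }
  genome
}

#' Simulate per-sample read recruitment
#'
#' Samples: three metagenomes and three metatranscriptomes (30/180/330 m
#' below the shelf base). Per-virus weights are log-normal, shared across
#' depths up to a small jitter (the community is planted depth-stable), with
#' one virus boosted `dominant_boost`-fold in metagenomes (dominant
#' abundance) and one in metatranscriptomes (dominant activity). Reads carry
#' binomial per-base errors; junk and mid-identity decoy reads exercise both
#' tier filters, and a fraction of genus-member reads gets a weaker
#' secondary hit to a genus mate to exercise best-hit deduplication.
#'
#' @param params [synth_params()]
#' @param viruses core viral [seq_set()]
#' @param truth truth object from [generate_viruses()] (updated and
#'   returned)
#' @return list with `samples`, `hits_by_sample`, `truth` (with
#'   `$abundance`: expected reads and KPKG per virus/sample/tier, and
#'   `$dominant`)
#' @export
generate_recruitment <- function(params, viruses, truth) {
  set.seed(params$seed + 37L)
  vids <- names(viruses)
  n <- length(vids)
  len_of <- setNames(nchar(unclass(viruses)), vids)
  samples <- data.frame(
    sample_id = c("MG_030", "MG_180", "MG_330", "MT_030", "MT_180", "MT_330"),
    kind = rep(c("metagenome", "metatranscriptome"), each = 3),
    dataset_size_bp = c(2.0e9, 1.8e9, 2.2e9, 1.2e9, 1.0e9, 1.1e9),
    depth = rep(c("30m", "180m", "330m"), 2),
    stringsAsFactors = FALSE)
  if (any(samples$dataset_size_bp <= 0)) stop("zero dataset size")
  w_base <- rlnorm(n, 0, 1)
  names(w_base) <- vids
  pair_vs <- names(truth$pair_type)
  dom_ab <- pair_vs[truth$pair_type == "crispr"][1]
  dom_ac <- pair_vs[truth$pair_type == "trna"][1]
  if (is.na(dom_ab)) dom_ab <- vids[1]
  if (is.na(dom_ac)) dom_ac <- vids[2]
  rl <- params$read_length
  hits_by_sample <- list()
  ab_rows <- list()
  p_species <- pbinom(floor(rl * 0.05), rl, params$error_rate)
  p_genus <- pbinom(floor(rl * 0.30), rl, params$error_rate)
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    w <- w_base * exp(rnorm(n, 0, 0.05))
    # the dominant virus is planted as such: boost relative to the largest
    # community weight so dominance is guaranteed, not merely likely
    if (samples$kind[si] == "metagenome") {
      w[dom_ab] <- params$dominant_boost * max(w_base)
    } else {
      w[dom_ac] <- params$dominant_boost * max(w_base)
    }
    p <- w / sum(w)
    counts <- as.vector(rmultinom(1, params$reads_per_sample, p))
    names(counts) <- vids
    rows <- list()
    ridx <- 0L
    for (v in vids) {
      cv <- counts[v]
      if (cv == 0) next
      errs <- rbinom(cv, rl, params$error_rate)
      sstart <- sample(len_of[v] - rl + 1, cv, replace = TRUE)
      ids <- sprintf("%s_r%06d", sid, ridx + seq_len(cv))
      ridx <- ridx + cv
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = ids, sseqid = v, pident = round(100 * (rl - errs) / rl, 2),
        length = rl, mismatch = errs, gapopen = 0L, qstart = 1L, qend = rl,
        sstart = sstart, send = sstart + rl - 1, evalue = 1e-50,
        bitscore = 2 * (rl - errs), qlen = rl, stringsAsFactors = FALSE)
      # secondary hits to a genus mate (weaker; removed by best-hit rule)
      mates <- setdiff(vids[truth$genus_of[vids] == truth$genus_of[v]], v)
      if (length(mates) > 0) {
        nsec <- rbinom(1, cv, params$secondary_hit_rate)
        if (nsec > 0) {
          sel <- sample(cv, nsec)
          mate <- sample(mates, nsec, replace = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(
            qseqid = ids[sel], sseqid = mate, pident = 75,
            length = rl, mismatch = round(rl * 0.25), gapopen = 0L,
            qstart = 1L, qend = rl,
            sstart = pmin(sstart[sel], len_of[mate] - rl + 1),
            send = pmin(sstart[sel], len_of[mate] - rl + 1) + rl - 1,
            evalue = 1e-20, bitscore = 2 * round(rl * 0.75), qlen = rl,
            stringsAsFactors = FALSE)
        }
      }
    }
    # junk reads: identity below the genus tier
    if (params$n_junk_reads > 0) {
      jv <- sample(vids, params$n_junk_reads, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = sprintf("%s_junk%05d", sid, seq_len(params$n_junk_reads)),
        sseqid = jv, pident = round(runif(params$n_junk_reads, 55, 65), 2),
        length = rl, mismatch = round(rl * 0.4), gapopen = 0L, qstart = 1L,
        qend = rl, sstart = 1L, send = rl, evalue = 1e-5,
        bitscore = round(rl * 0.6), qlen = rl, stringsAsFactors = FALSE)
    }
    # mid reads: pass the genus tier only (id 80, coverage 60%)
    mid_per_virus <- params$n_mid_reads / n
    if (params$n_mid_reads > 0) {
      mv <- sample(vids, params$n_mid_reads, replace = TRUE)
      qe <- round(rl * 0.6)
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = sprintf("%s_mid%05d", sid, seq_len(params$n_mid_reads)),
        sseqid = mv, pident = 80, length = qe, mismatch = round(qe * 0.2),
        gapopen = 0L, qstart = 1L, qend = qe, sstart = 1L, send = qe,
        evalue = 1e-10, bitscore = round(qe * 1.2), qlen = rl,
        stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, rows)
    row.names(hits) <- NULL
    hits_by_sample[[sid]] <- hits
    exp_reads <- params$reads_per_sample * p
    D <- samples$dataset_size_bp[si]
    ab_rows[[length(ab_rows) + 1L]] <- data.frame(
      virus_id = rep(vids, 2), sample_id = sid,
      tier = rep(c("species", "genus"), each = n),
      expected_reads = c(exp_reads * p_species,
                         exp_reads * p_genus + mid_per_virus),
      expected_kpkg = c(
        compute_kpkg(exp_reads * p_species * rl, len_of, D),
        compute_kpkg(exp_reads * p_genus * rl + mid_per_virus * rl * 0.6,
                     len_of, D)),
      stringsAsFactors = FALSE)
  }
  truth$abundance <- do.call(rbind, ab_rows)
  row.names(truth$abundance) <- NULL
  truth$dominant <- list(abundance = dom_ab, activity = dom_ac)
  list(samples = samples, hits_by_sample = hits_by_sample, truth = truth)
}

#' Simulate a full synthetic community
#'
#' Runs [generate_hosts()], [generate_viruses()] and (optionally)
#' [generate_recruitment()] under one seed and, when `dir` is given, writes
#' every table/FASTA plus `truth.json` and a manifest.
#'
#' @param params [synth_params()]
#' @param dir optional output directory
#' @param recruitment simulate read recruitment too? (default TRUE)
#' @return list with all generated components and `truth`
#' @export
simulate_community <- function(params, dir = NULL, recruitment = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  iv_log("generating %d hosts", params$n_hosts)
  hosts <- generate_hosts(params)
  iv_log("generating %d viruses (+8 triage decoys)", params$n_viruses)
  vir <- generate_viruses(params, hosts)
  out <- vir
  out$hosts <- vir$hosts
  out$params <- params
  if (recruitment) {
    iv_log("simulating read recruitment")
    rec <- generate_recruitment(params, vir$viruses, vir$truth)
    out$samples <- rec$samples
    out$hits_by_sample <- rec$hits_by_sample
    out$truth <- rec$truth
  }
  if (!is.null(dir)) write_community(out, dir)
  out
}

write_community <- function(com, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_fasta(com$hosts$seqs, fp("hosts.fna"))
  allv <- seq_set(c(unclass(com$viruses), unclass(com$decoy_seqs)), "dna")
  write_fasta(allv, fp("viruses.fna"))
  write_fasta(com$proteins, fp("proteins_virus.faa"))
  hostprot <- seq_set(unlist(com$hosts$proteins), "protein")
  names(hostprot) <- unlist(lapply(com$hosts$proteins, names))
  write_fasta(hostprot, fp("proteins_host.faa"))
  if (length(com$trnas) > 0) write_fasta(com$trnas, fp("viral_trnas.fna"))
  data.table::fwrite(com$screen, fp("screen_table.tsv"), sep = "\t")
  write_hits(com$hits_protein, fp("hits_protein_allvsall.tsv"))
  write_hits(com$hits_amg, fp("hits_amg.tsv"))
  write_hits(com$pair_hits_nt, fp("hits_nucleotide_pairs.tsv"))
  data.table::fwrite(com$bins, fp("bins.tsv"), sep = "\t")
  data.table::fwrite(com$annotations, fp("annotations.tsv"), sep = "\t")
  map <- data.frame(protein_id = names(com$protein_virus),
                    genome_id = unname(com$protein_virus))
  data.table::fwrite(map, fp("protein_to_genome.tsv"), sep = "\t")
  files <- c("hosts.fna", "viruses.fna", "proteins_virus.faa",
             "proteins_host.faa", "screen_table.tsv",
             "hits_protein_allvsall.tsv", "hits_amg.tsv",
             "hits_nucleotide_pairs.tsv", "bins.tsv", "annotations.tsv",
             "protein_to_genome.tsv")
  if (!is.null(com$samples)) {
    data.table::fwrite(com$samples, fp("samples.tsv"), sep = "\t")
    files <- c(files, "samples.tsv")
    for (sid in names(com$hits_by_sample)) {
      f <- sprintf("recruitment_%s.tsv", sid)
      write_hits(com$hits_by_sample[[sid]], fp(f))
      files <- c(files, f)
    }
  }
  jsonlite::write_json(com$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- list(seed = com$params$seed,
                   params = unclass(com$params),
                   files = as.list(setNames(
                     unname(tools::md5sum(vapply(files, fp, ""))), files)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
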