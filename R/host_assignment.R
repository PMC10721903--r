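# Multi-evidence virus-host assignment.
#
# Strong evidence: CRISPR spacer-protospacer matches, shared tRNAs, AMG
# homology. Supporting evidence: k-mer Markov log-likelihood (WisH-style),
# codon-usage distance, binning co-occurrence. Binning alone never yields an
# assignment: binners can misplace a viral contig on %GC or coverage alone.

EVIDENCE_STRONG <- c("crispr", "trna", "amg")
EVIDENCE_SUPPORTING <- c("wish", "codon", "binning")

evidence_frame <- function(virus_id = character(0), host_id = character(0),
                           etype = character(0), score = numeric(0),
                           passed = logical(0), detail = character(0)) {
  data.frame(virus_id = unname(virus_id), host_id = unname(host_id),
             etype = unname(etype), score = unname(score),
             passed = unname(passed), detail = unname(detail),
             stringsAsFactors = FALSE)
}

# ---- CRISPR arrays ---------------------------------------------------------

#' Detect CRISPR arrays in host genomes
#'
#' CRT-style detection: exact seed k-mers (length = minimum repeat length)
#' recurring with period repeat+spacer are chained into candidate arrays and
#' the repeat is extended outward while all copies agree, bounded by the
#' repeat/spacer length windows. Because an exact repeat array reads as an
#' exact repeat array on both strands, a forward-strand scan finds arrays of
#' either orientation; coordinates are reported on the forward strand and
#' spacers in forward orientation (protospacer matching searches both strands
#' of each spacer downstream).
#'
#' Copies are required to match the seed exactly; `max_repeat_mismatch`
#' divergence from the consensus is only tolerated outside the seed, so
#' heavily degenerate repeats can be missed (planted and typical natural
#' arrays have near-identical copies).
#'
#' @param hosts a [seq_set()] of DNA genomes (or a single named sequence)
#' @param min_repeats minimum repeat copies (default 3)
#' @param repeat_len,spacer_len allowed length windows (defaults 19-38 and
#'   19-48 bp)
#' @param max_repeat_mismatch tolerated per-copy mismatches vs the consensus
#' @return list of arrays; each is a list with `host_id`, `repeat_consensus`,
#'   `repeat_len`, `repeat_starts` (1-based forward coordinates of each
#'   copy), `spacers` (character), `spacer_starts`, `n_copies`
#' @export
detect_crispr <- function(hosts, min_repeats = 3, repeat_len = c(19, 38),
                          spacer_len = c(19, 48), max_repeat_mismatch = 1) {
  if (!inherits(hosts, "seq_set")) hosts <- seq_set(hosts, "dna")
  if (identical(attr(hosts, "moltype"), "protein")) stop("DNA input required")
  out <- list()
  for (hid in names(hosts)) {
    arrays <- crispr_scan_one(unname(hosts[[hid]]), min_repeats, repeat_len,
                              spacer_len, max_repeat_mismatch)
    for (a in arrays) {
      a$host_id <- hid
      out[[length(out) + 1L]] <- a
    }
  }
  out
}

crispr_scan_one <- function(s, min_repeats, repeat_len, spacer_len,
                            max_mm) {
  L <- nchar(s)
  seed <- repeat_len[1]
  if (L < min_repeats * seed) return(list())
  min_period <- repeat_len[1] + spacer_len[1]
  max_period <- repeat_len[2] + spacer_len[2]
  starts <- seq_len(L - seed + 1)
  kmers <- substring(s, starts, starts + seed - 1)
  dt <- data.table::data.table(kmer = kmers, pos = starts)
  counts <- dt[, list(n = .N), by = "kmer"]
  cand <- counts$kmer[counts$n >= min_repeats & !grepl("N", counts$kmer)]
  if (length(cand) == 0) return(list())
  arrays <- list()
  seen <- character(0)
  for (km in cand) {
    p <- sort(dt$pos[dt$kmer == km])
    for (chain in chain_positions(p, min_period, max_period)) {
      if (length(chain) < min_repeats) next
      a <- extend_array(s, chain, seed, repeat_len, spacer_len, min_repeats)
      if (is.null(a)) next
      key <- paste(a$repeat_starts, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      arrays[[length(arrays) + 1L]] <- a
    }
  }
  suppress_overlaps(arrays)
}

# shifted sub-arrays (e.g. when every spacer starts with the same base) can
# be emitted alongside the full array; keep the best-supported array per
# locus (most copies, then longest repeat, then leftmost)
suppress_overlaps <- function(arrays) {
  if (length(arrays) <= 1) return(arrays)
  span <- t(vapply(arrays, function(a) {
    c(a$repeat_starts[1], a$repeat_starts[a$n_copies] + a$repeat_len - 1)
  }, numeric(2)))
  o <- order(-vapply(arrays, `[[`, 0, "n_copies"),
             -vapply(arrays, `[[`, 0, "repeat_len"), span[, 1])
  kept <- integer(0)
  for (i in o) {
    clash <- any(span[kept, 1] <= span[i, 2] & span[kept, 2] >= span[i, 1])
    if (!clash) kept <- c(kept, i)
  }
  arrays[sort(kept)]
}

# split sorted positions into maximal runs whose successive gaps lie in
# [min_period, max_period]
chain_positions <- function(p, min_period, max_period) {
  if (length(p) == 0) return(list())
  d <- diff(p)
  ok <- d >= min_period & d <= max_period
  breaks <- c(0, which(!ok), length(p))
  lapply(seq_len(length(breaks) - 1), function(i) {
    p[(breaks[i] + 1):breaks[i + 1]]
  })
}

extend_array <- function(s, p, seed, repeat_len, spacer_len, min_repeats) {
  L <- nchar(s)
  gaps <- diff(p)
  # extend right from the seed end while every copy shows the same base
  right <- 0
  repeat {
    if (seed + right >= repeat_len[2]) break
    idx <- p + seed + right
    if (max(idx) > L) break
    ch <- substring(s, idx, idx)
    if (length(unique(ch)) != 1 || ch[1] == "N") break
    if (min(gaps) - (seed + right + 1) < spacer_len[1]) break
    right <- right + 1
  }
  left <- 0
  repeat {
    if (seed + right + left >= repeat_len[2]) break
    idx <- p - left - 1
    if (min(idx) < 1) break
    ch <- substring(s, idx, idx)
    if (length(unique(ch)) != 1 || ch[1] == "N") break
    if (min(gaps) - (seed + right + left + 1) < spacer_len[1]) break
    left <- left + 1
  }
  rep_len <- seed + left + right
  starts <- p - left
  sp_lens <- diff(starts) - rep_len
  if (rep_len < repeat_len[1] || rep_len > repeat_len[2]) return(NULL)
  if (any(sp_lens < spacer_len[1] | sp_lens > spacer_len[2])) return(NULL)
  if (length(starts) < min_repeats) return(NULL)
  sp_starts <- starts[-length(starts)] + rep_len
  spacers <- substring(s, sp_starts, sp_starts + sp_lens - 1)
  list(repeat_consensus = substring(s, starts[1], starts[1] + rep_len - 1),
       repeat_len = rep_len, repeat_starts = starts, n_copies = length(starts),
       spacers = spacers, spacer_starts = sp_starts)
}

# ---- spacer-protospacer matching -------------------------------------------

#' Match CRISPR spacers against viral genomes
#'
#' Each spacer is aligned against each virus on both strands with
#' [smith_waterman()]; evidence passes when the best alignment spans the full
#' spacer with no gaps and at most `max_mismatches` mismatches. An exact-seed
#' prefilter (pigeonhole bound: a qualifying match must contain an exact run
#' of `floor((L - m)/(m + 1))` bases) skips virus genomes that cannot
#' possibly contain a qualifying protospacer; it is bypassed when the derived
#' seed would be shorter than 10 bp.
#'
#' @param arrays list from [detect_crispr()]
#' @param viruses a [seq_set()] of viral genomes
#' @param max_mismatches tolerated mismatches over the full spacer length
#' @param sw list of Smith-Waterman scores (`match`, `mismatch`, `gap`)
#' @return evidence data.frame (`etype = "crispr"`, score = mismatch count;
#'   lower is better) with one row per spacer/virus alignment examined
#' @export
match_spacers <- function(arrays, viruses, max_mismatches = 1,
                          sw = list(match = 1, mismatch = -1, gap = -2)) {
  if (length(arrays) == 0) return(evidence_frame())
  sp <- do.call(rbind, lapply(arrays, function(a) {
    if (length(a$spacers) == 0) return(NULL)
    data.frame(host_id = a$host_id, spacer = a$spacers,
               stringsAsFactors = FALSE)
  }))
  if (is.null(sp) || nrow(sp) == 0) return(evidence_frame())
  sp <- sp[nchar(sp$spacer) >= 19, , drop = FALSE]
  vset <- Biostrings::DNAStringSet(unclass(viruses))
  rows <- list()
  for (i in seq_len(nrow(sp))) {
    spacer <- sp$spacer[i]
    L <- nchar(spacer)
    seed_len <- floor((L - max_mismatches) / (max_mismatches + 1))
    cand <- if (seed_len >= 10) {
      seed_candidates(spacer, seed_len, vset)
    } else seq_along(vset)
    for (vi in cand) {
      hit <- smith_waterman(setNames(spacer, "spacer"),
                            setNames(as.character(vset[[vi]]),
                                     names(vset)[vi]),
                            moltype = "dna", match = sw$match,
                            mismatch = sw$mismatch, gap = sw$gap)
      if (is.null(hit)) next
      passed <- hit$length == L && hit$gaps == 0 &&
        hit$mismatch <= max_mismatches
      rows[[length(rows) + 1L]] <- evidence_frame(
        virus_id = names(vset)[vi], host_id = sp$host_id[i],
        etype = "crispr", score = hit$mismatch, passed = passed,
        detail = sprintf("spacer=%s strand=%s s=%d-%d aln=%d mm=%d",
                         spacer, hit$strand, hit$sstart, hit$send,
                         hit$length, hit$mismatch))
    }
  }
  if (length(rows) == 0) return(evidence_frame())
  do.call(rbind, rows)
}

# indices of set members containing any length-`seed_len` substring of
# `pattern` (either strand)
seed_candidates <- function(pattern, seed_len, vset) {
  n <- nchar(pattern)
  subs <- substring(pattern, 1:(n - seed_len + 1), seed_len:n)
  subs <- unique(c(subs, as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(subs)))))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(subs))
  hits <- Biostrings::vwhichPDict(pd, vset)
  which(lengths(hits) > 0)
}

# ---- tRNA matching ---------------------------------------------------------

#' Match viral tRNAs against host genomes
#'
#' Local alignment of each viral tRNA against each host genome (both
#' strands); evidence passes with alignment length >= 60 bp, identity >= 97%
#' and fewer than 10 mismatches.
#'
#' @param trnas [seq_set()] of viral tRNA sequences
#' @param hosts [seq_set()] of host genomes
#' @param trna_virus named character vector mapping tRNA id -> virus id
#' @param min_aln,min_identity,max_mismatch thresholds (mismatches must be
#'   strictly below `max_mismatch`)
#' @param sw Smith-Waterman scores
#' @return evidence data.frame (`etype = "trna"`, score = percent identity)
#' @export
match_trna <- function(trnas, hosts, trna_virus, min_aln = 60,
                       min_identity = 97, max_mismatch = 10,
                       sw = list(match = 1, mismatch = -1, gap = -2)) {
  if (length(trnas) == 0) return(evidence_frame())
  miss <- setdiff(names(trnas), names(trna_virus))
  if (length(miss) > 0) stop("no virus mapping for tRNA(s): ",
                             paste(miss, collapse = ", "))
  rows <- list()
  for (ti in names(trnas)) {
    for (hi in names(hosts)) {
      hit <- smith_waterman(trnas[ti], hosts[hi], moltype = "dna",
                            match = sw$match, mismatch = sw$mismatch,
                            gap = sw$gap)
      if (is.null(hit) || hit$length < 20) next
      passed <- hit$length >= min_aln && hit$pident >= min_identity &&
        hit$mismatch < max_mismatch
      rows[[length(rows) + 1L]] <- evidence_frame(
        virus_id = unname(trna_virus[ti]), host_id = hi, etype = "trna",
        score = hit$pident, passed = passed,
        detail = sprintf("trna=%s aln=%d id=%.1f mm=%d strand=%s",
                         ti, hit$length, hit$pident, hit$mismatch,
                         hit$strand))
    }
  }
  if (length(rows) == 0) return(evidence_frame())
  do.call(rbind, rows)
}

# ---- WisH-style k-mer Markov likelihood ------------------------------------

#' Train an order-(k-1) Markov model on a host genome
#'
#' Counts k-mers on both strands with add-`pseudocount` smoothing and stores
#' natural-log conditional probabilities of each base given the preceding
#' (k-1)-mer context.
#'
#' @param genome a single DNA sequence (named character or [seq_set()] of 1)
#' @param k k-mer length (default 8, the convention of WisH-style tools)
#' @param pseudocount additive smoothing (default 1)
#' @return a `markov_model`: list with `host_id`, `k`, `pseudocount`, `logp`
#'   (matrix of 4^(k-1) contexts x 4 bases; rows sum to 1 on the probability
#'   scale)
#' @export
train_markov <- function(genome, k = 8, pseudocount = 1) {
  hid <- names(genome)[1] %||% "host"
  s <- toupper(unname(unclass(genome)[1]))
  if (!all(strsplit(s, "")[[1]] %in% DNA_ALPHABET)) stop("DNA input required")
  if (nchar(s) < 16 * k) {
    warning("genome shorter than ", 16 * k, " bp: model will be dominated ",
            "by the pseudocount")
  }
  x <- Biostrings::DNAString(s)
  counts <- Biostrings::oligonucleotideFrequency(x, width = k) +
    Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(x),
                                         width = k)
  C <- matrix(counts, ncol = 4, byrow = TRUE)
  contexts <- substr(names(counts)[seq(1, length(counts), by = 4)], 1, k - 1)
  dimnames(C) <- list(contexts, c("A", "C", "G", "T"))
  logp <- log((C + pseudocount) / (rowSums(C) + 4 * pseudocount))
  structure(list(host_id = hid, k = k, pseudocount = pseudocount,
                 logp = logp),
            class = "markov_model")
}

#' Uniform (order-0) null model
#' @param k nominal k-mer length (context is ignored; every base has
#'   probability 1/4)
#' @return a `markov_model`
#' @export
uniform_markov <- function(k = 8) {
  nc <- 4^(k - 1)
  logp <- matrix(log(0.25), nc, 4)
  colnames(logp) <- c("A", "C", "G", "T")
  structure(list(host_id = "uniform", k = k, pseudocount = 0, logp = logp),
            class = "markov_model")
}

#' Mean per-nucleotide log-likelihood of viral sequences under host models
#'
#' For each sequence, the mean over k-mer windows of
#' `ln P(base | preceding context)` under the trained model; evidence passes
#' when the value falls inside `window` (default `[-1.30, -1.20]`,
#' inclusive).
#'
#' @param models a `markov_model` or list of them (all with the same `k`)
#' @param seqs [seq_set()] or named character vector of viral DNA
#' @param window pass window (inclusive)
#' @return data.frame `virus_id`, `host_id`, `etype = "wish"`,
#'   `score` (the log-likelihood), `passed`, `detail`
#' @export
wish_loglik <- function(models, seqs, window = c(-1.30, -1.20)) {
  if (inherits(models, "markov_model")) models <- list(models)
  k <- models[[1]]$k
  stopifnot(all(vapply(models, function(m) m$k, 0) == k))
  ll <- wish_matrix(models, seqs)
  hostids <- unname(vapply(models, function(m) m$host_id, ""))
  out <- expand.grid(virus_id = rownames(ll), host_id = hostids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$etype <- "wish"
  out$score <- as.vector(ll)
  out$passed <- out$score >= window[1] & out$score <= window[2]
  out$detail <- sprintf("k=%d loglik=%.4f", k, out$score)
  out[, c("virus_id", "host_id", "etype", "score", "passed", "detail")]
}

# matrix of mean log-likelihoods: sequences x models (chunked so the dense
# k-mer count matrix stays small)
wish_matrix <- function(models, seqs, chunk = 64L) {
  k <- models[[1]]$k
  lpmat <- vapply(models, function(m) as.vector(t(m$logp)),
                  numeric(4^k))
  x <- Biostrings::DNAStringSet(unclass(seqs))
  if (any(Biostrings::width(x) < k)) stop("sequence shorter than k")
  n <- length(x)
  out <- matrix(NA_real_, n, length(models),
                dimnames = list(names(x),
                                vapply(models, function(m) m$host_id, "")))
  for (i0 in seq(1, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1, n)
    cnt <- Biostrings::oligonucleotideFrequency(x[idx], width = k)
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1)
    tot <- rowSums(cnt)
    out[idx, ] <- (cnt %*% lpmat) / tot
  }
  out
}

# ---- codon usage -----------------------------------------------------------

#' Codon usage frequencies of a CDS collection
#'
#' Sequences are trimmed to a multiple of 3 (with a warning when bases are
#' dropped) and codons counted in frame; frequencies sum to 1 over the 64
#' codons.
#'
#' @param cds character vector (or [seq_set()]) of coding sequences
#' @return named numeric vector of 64 codon frequencies
#' @export
codon_usage <- function(cds) {
  cds <- toupper(unclass(cds))
  if (length(cds) == 0 || all(!nzchar(cds))) stop("empty CDS input")
  trimmed <- nchar(cds) %% 3
  if (any(trimmed > 0)) {
    warning(sum(trimmed > 0), " CDS length(s) not a multiple of 3; ",
            "trailing bases dropped")
    cds <- substr(cds, 1, nchar(cds) - trimmed)
  }
  cds <- cds[nchar(cds) >= 3]
  if (length(cds) == 0) stop("no complete codons in input")
  counts <- Reduce(`+`, lapply(cds, function(s) {
    Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                         width = 3, step = 3)
  }))
  if (sum(counts) == 0) stop("no countable codons (all ambiguous?)")
  counts / sum(counts)
}

#' Euclidean distance between two codon-usage tables
#' @param table_v,table_h 64-entry frequency vectors from [codon_usage()]
#' @return numeric distance
#' @export
codon_distance <- function(table_v, table_h) {
  stopifnot(length(table_v) == 64, length(table_h) == 64)
  sqrt(sum((table_v - table_h)^2))
}

#' Codon-usage evidence for all virus/host combinations
#'
#' @param viral_cds named list: virus id -> character vector of CDS
#' @param host_cds named list: host id -> character vector of CDS
#' @param cutoff pass distance (default 0.05); codon usage is supporting
#'   evidence only
#' @return evidence data.frame (`etype = "codon"`, score = distance)
#' @export
codon_evidence <- function(viral_cds, host_cds, cutoff = 0.05) {
  tv <- lapply(viral_cds, codon_usage)
  th <- lapply(host_cds, codon_usage)
  out <- expand.grid(virus_id = names(tv), host_id = names(th),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$etype <- "codon"
  out$score <- unname(mapply(function(v, h) codon_distance(tv[[v]], th[[h]]),
                             out$virus_id, out$host_id))
  out$passed <- out$score <= cutoff
  out$detail <- sprintf("euclidean=%.4f", out$score)
  out
}

# ---- AMG detection ---------------------------------------------------------

#' Detect auxiliary metabolic genes from viral-vs-host protein hits
#'
#' A viral ORF is a putative AMG of a host gene when the hit has e-value
#' better than 5e-5 and both identity and query coverage >= 50%. Each
#' passing (viral ORF, host gene) pair is also host evidence.
#'
#' @param hits viral-protein (query) vs host-protein (subject) hit table
#' @param protein_virus named vector: viral protein id -> virus id
#' @param protein_host named vector: host protein id -> host id
#' @param max_evalue,min_identity,min_qcov thresholds (e-value strictly
#'   better than `max_evalue`)
#' @param qlen optional query-length lookup
#' @return list with `amgs` (data.frame of passing pairs) and `evidence`
#'   (one row per virus/host pair examined, `etype = "amg"`)
#' @export
detect_amg <- function(hits, protein_virus, protein_host,
                       max_evalue = 5e-5, min_identity = 50, min_qcov = 50,
                       qlen = NULL) {
  if (nrow(hits) == 0) {
    return(list(amgs = data.frame(viral_orf = character(0),
                                  host_gene = character(0),
                                  virus_id = character(0),
                                  host_id = character(0)),
                evidence = evidence_frame()))
  }
  qcov <- query_coverage(hits, qlen)
  pass <- hits$evalue < max_evalue & hits$pident >= min_identity &
    qcov >= min_qcov
  vir <- unname(protein_virus[hits$qseqid])
  hos <- unname(protein_host[hits$sseqid])
  if (any(is.na(vir))) stop("unmapped viral protein(s): ",
                            paste(unique(hits$qseqid[is.na(vir)]), collapse = ", "))
  if (any(is.na(hos))) stop("unmapped host protein(s): ",
                            paste(unique(hits$sseqid[is.na(hos)]), collapse = ", "))
  amgs <- data.frame(viral_orf = hits$qseqid[pass],
                     host_gene = hits$sseqid[pass],
                     virus_id = vir[pass], host_id = hos[pass],
                     pident = hits$pident[pass], qcov = qcov[pass],
                     evalue = hits$evalue[pass],
                     stringsAsFactors = FALSE)
  amgs <- amgs[!duplicated(amgs[, c("viral_orf", "host_gene")]), ,
               drop = FALSE]
  pair <- data.frame(virus_id = vir, host_id = hos, passed = pass,
                     pident = hits$pident, stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(
    split(pair, paste(pair$virus_id, pair$host_id, sep = "\r")),
    function(p) data.frame(virus_id = p$virus_id[1], host_id = p$host_id[1],
                           passed = any(p$passed), score = max(p$pident),
                           n = nrow(p), stringsAsFactors = FALSE)))
  ev <- evidence_frame(virus_id = agg$virus_id, host_id = agg$host_id,
                       etype = rep("amg", nrow(agg)), score = agg$score,
                       passed = agg$passed,
                       detail = sprintf("%d hit(s), best id=%.1f%%",
                                        agg$n, agg$score))
  list(amgs = amgs, evidence = ev)
}

#' Binning co-occurrence evidence
#'
#' Presence of a viral contig in a host bin. Always supporting-only:
#' [integrate_evidence()] never assigns a host from binning alone.
#'
#' @param bins data.frame with `virus_id`, `bin_id`
#' @param bin_host named vector: bin id -> host id
#' @return evidence data.frame (`etype = "binning"`)
#' @export
binning_evidence <- function(bins, bin_host) {
  if (nrow(bins) == 0) return(evidence_frame())
  host <- unname(bin_host[bins$bin_id])
  keep <- !is.na(host)
  evidence_frame(virus_id = bins$virus_id[keep], host_id = host[keep],
                 etype = rep("binning", sum(keep)),
                 score = rep(1, sum(keep)), passed = rep(TRUE, sum(keep)),
                 detail = paste0("bin=", bins$bin_id[keep]))
}

# ---- integration -----------------------------------------------------------

#' Integrate evidence into per-virus host assignments
#'
#' Per candidate host: tier `"strong"` with >= 1 passed evidence item of type
#' crispr, trna or amg; tier `"supporting"` with >= 2 passed items among
#' wish, codon and binning; otherwise unassigned. Among competing hosts the
#' one with most passed strong items wins, ties broken by most passed items
#' overall; a remaining tie leaves the virus unassigned with an ambiguity
#' flag. Binning alone (or any single supporting item) never assigns.
#'
#' @param evidence data.frame of evidence rows (rbind of the `*_evidence` /
#'   matching outputs)
#' @param viruses optional character vector of all virus ids so that viruses
#'   without evidence appear as unassigned rows
#' @return data.frame `virus_id`, `host_id` (`NA` when unassigned), `tier`,
#'   `n_strong`, `n_supporting`, `ambiguous`
#' @export
integrate_evidence <- function(evidence, viruses = NULL) {
  all_virus <- union(viruses, unique(evidence$virus_id))
  res <- lapply(all_virus, function(v) {
    ev <- evidence[evidence$virus_id == v & evidence$passed, , drop = FALSE]
    base <- data.frame(virus_id = v, host_id = NA_character_,
                       tier = "unassigned", n_strong = 0L, n_supporting = 0L,
                       ambiguous = FALSE, stringsAsFactors = FALSE)
    if (nrow(ev) == 0) return(base)
    per_host <- do.call(rbind, lapply(split(ev, ev$host_id), function(e) {
      data.frame(host_id = e$host_id[1],
                 n_strong = sum(e$etype %in% EVIDENCE_STRONG),
                 n_supporting = sum(e$etype %in% EVIDENCE_SUPPORTING),
                 n_total = nrow(e), stringsAsFactors = FALSE)
    }))
    strong <- per_host[per_host$n_strong >= 1, , drop = FALSE]
    if (nrow(strong) > 0) {
      pick <- pick_host(strong, strong$n_strong)
      if (is.null(pick)) { base$ambiguous <- TRUE; return(base) }
      base$host_id <- pick$host_id
      base$tier <- "strong"
      base$n_strong <- pick$n_strong
      base$n_supporting <- pick$n_supporting
      return(base)
    }
    supp <- per_host[per_host$n_supporting >= 2, , drop = FALSE]
    if (nrow(supp) > 0) {
      pick <- pick_host(supp, supp$n_supporting)
      if (is.null(pick)) { base$ambiguous <- TRUE; return(base) }
      base$host_id <- pick$host_id
      base$tier <- "supporting"
      base$n_supporting <- pick$n_supporting
      return(base)
    }
    base
  })
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}

pick_host <- function(per_host, primary) {
  cand <- per_host[primary == max(primary), , drop = FALSE]
  if (nrow(cand) > 1) {
    cand <- cand[cand$n_total == max(cand$n_total), , drop = FALSE]
  }
  if (nrow(cand) > 1) return(NULL)
  cand
}
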