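# Fragment-recruitment abundance/activity: dual-tier identity-and-coverage
# filtering of read hits, KPKG normalisation, per-sample profiles and top-N
# rankings.
#
# Tiers: species-level recruitment keeps identity >= 95% and query coverage
# >= 85%; genus-level keeps identity >= 70% and coverage >= 50%. Reads are
# deduplicated to their best hit (highest bitscore, ties to the
# lexicographically smallest subject) *before* tier filtering, so the
# species-tier retained set is always nested inside the genus-tier set.

TIER_THRESHOLDS <- list(species = c(min_identity = 95, min_qcov = 85),
                        genus = c(min_identity = 70, min_qcov = 50))

#' Filter recruitment hits at one identity tier
#'
#' @param hits read-vs-contig hit table (outfmt-6 layout; reads are queries)
#' @param tier `"species"` (>= 95% id, >= 85% qcov) or `"genus"` (>= 70% id,
#'   >= 50% qcov)
#' @param qlen optional named read-length lookup for rows lacking `qlen`
#' @return the retained hit rows, one per read at most
#' @export
filter_recruits <- function(hits, tier = c("species", "genus"), qlen = NULL) {
  tier <- match.arg(tier)
  if (nrow(hits) == 0) return(hits)
  best <- best_hit_per_read(hits)
  thr <- TIER_THRESHOLDS[[tier]]
  qcov <- query_coverage(best, qlen)
  best[best$pident >= thr[["min_identity"]] & qcov >= thr[["min_qcov"]], ,
       drop = FALSE]
}

best_hit_per_read <- function(hits) {
  o <- order(hits$qseqid, -hits$bitscore, hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' KPKG: recruited kilobases per genome kilobase per gigabase of dataset
#'
#' `(recruited_bp / 1e3) / (genome_len_bp / 1e3) / (dataset_size_bp / 1e9)`.
#'
#' @param recruited_bp aligned bases recruited to the genome
#' @param genome_len_bp contig/genome length (> 0)
#' @param dataset_size_bp metagenome or metatranscriptome size in bp (> 0)
#' @return numeric KPKG (vectorised)
#' @export
compute_kpkg <- function(recruited_bp, genome_len_bp, dataset_size_bp) {
  if (any(genome_len_bp <= 0)) stop("genome length must be positive")
  if (any(dataset_size_bp <= 0)) stop("dataset size must be positive")
  if (any(recruited_bp < 0)) stop("recruited_bp must be >= 0")
  (recruited_bp / 1e3) / (genome_len_bp / 1e3) / (dataset_size_bp / 1e9)
}

#' Per-virus, per-sample recruitment profile
#'
#' Sums aligned bases of retained best-hits per (contig, sample), normalises
#' to KPKG, and labels metagenome samples "abundance" and metatranscriptome
#' samples "activity".
#'
#' @param hits_by_sample named list of hit tables, one per sample id
#' @param contig_lengths named vector of contig lengths in bp
#' @param samples data.frame with `sample_id`, `kind`
#'   ("metagenome"/"metatranscriptome"), `dataset_size_bp`, optional `depth`
#' @param tier recruitment tier, see [filter_recruits()]
#' @param qlen optional read-length lookup
#' @return data.frame `contig_id`, `sample_id`, `kind`, `measure`, `tier`,
#'   `recruited_bp`, `kpkg` (every contig x sample combination, zeros kept)
#' @export
recruitment_profile <- function(hits_by_sample, contig_lengths, samples,
                                tier = c("species", "genus"), qlen = NULL) {
  tier <- match.arg(tier)
  stopifnot(all(c("sample_id", "kind", "dataset_size_bp") %in% names(samples)))
  miss <- setdiff(samples$sample_id, names(hits_by_sample))
  if (length(miss) > 0) stop("no hit table for sample(s): ",
                             paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    hits <- hits_by_sample[[sid]]
    kept <- filter_recruits(hits, tier, qlen)
    unknown <- setdiff(unique(kept$sseqid), names(contig_lengths))
    if (length(unknown) > 0) {
      stop("hits to unknown contig(s) in ", sid, ": ",
           paste(unknown, collapse = ", "))
    }
    bp <- tapply(kept$length, kept$sseqid, sum)
    rec <- setNames(numeric(length(contig_lengths)), names(contig_lengths))
    rec[names(bp)] <- bp
    data.frame(
      contig_id = names(rec), sample_id = sid, kind = samples$kind[i],
      measure = ifelse(samples$kind[i] == "metatranscriptome",
                       "activity", "abundance"),
      tier = tier, recruited_bp = unname(rec),
      kpkg = compute_kpkg(unname(rec), unname(contig_lengths[names(rec)]),
                          samples$dataset_size_bp[i]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Top-N contigs per sample by KPKG
#'
#' @param profile data.frame from [recruitment_profile()]
#' @param n how many per sample (default 3, as in top-3 abundance/activity
#'   rankings)
#' @return data.frame of the top rows with a `rank` column; descending KPKG,
#'   ties broken by contig id
#' @export
top_viruses <- function(profile, n = 3) {
  if (nrow(profile) == 0) stop("empty profile")
  out <- lapply(split(profile, profile$sample_id), function(p) {
    p <- p[order(-p$kpkg, p$contig_id), , drop = FALSE]
    p <- head(p, n)
    p$rank <- seq_len(nrow(p))
    p
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
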