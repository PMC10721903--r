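# Three-round triage of candidate viral contigs.
#
# Round 1: per-class length cutoffs. Round 2: hallmark-gene and host:viral
# gene-ratio rules, relaxed for proviruses; contigs carrying no information
# (0 hallmark, 0 host genes) are discarded. Round 3: an origin-score screen
# (PPR-meta-like score), optional and configurable.

VIRAL_CLASSES <- c("dsDNA", "ssDNA", "RNA", "NCLDV", "Lavidaviridae")

TRIAGE_RULES <- c("length_cutoff", "zero_information", "no_hallmark",
                  "host_viral_ratio", "origin_screen", "pass")

#' Minimum contig length per predicted viral class
#'
#' dsDNA, NCLDV and Lavidaviridae candidates must reach 10 kb; RNA and ssDNA
#' viruses have genuinely small genomes and get lower cutoffs (1.5 kb and
#' 2.5 kb).
#'
#' @param viral_class character vector of class labels
#' @return numeric vector of cutoffs in bp
#' @export
length_cutoff <- function(viral_class) {
  cutoffs <- c(dsDNA = 10000, NCLDV = 10000, Lavidaviridae = 10000,
               RNA = 1500, ssDNA = 2500)
  bad <- setdiff(unique(viral_class), names(cutoffs))
  if (length(bad) > 0) {
    stop("unknown viral class(es): ", paste(bad, collapse = ", "))
  }
  unname(cutoffs[viral_class])
}

#' Triage decision for one screening record
#'
#' Rules fire in a fixed order: (1) length below the class cutoff; (2) zero
#' information (no hallmark genes and no host genes); (3) proviruses are
#' accepted with >= 1 hallmark gene, the ratio rule being waived; (4) other
#' contigs need >= 1 hallmark gene and a host:viral gene ratio < 1; (5) an
#' accepted contig is still rejected if its viral-origin score falls below
#' `min_origin_score` (set to 0 or `NA` to disable the third round).
#'
#' Hallmark genes count as viral genes, so the ratio denominator is
#' `max(viral_gene_count, hallmark_count, 1)`.
#'
#' @param rec list or one-row data.frame with fields `contig_id`, `length`,
#'   `viral_class`, `hallmark_count`, `viral_gene_count`, `host_gene_count`,
#'   `is_provirus`, `viral_origin_score`
#' @param min_origin_score third-round screen threshold (default 0.5)
#' @return list with `contig_id`, `verdict` ("accepted"/"rejected") and
#'   `rule_fired`
#' @export
classify_contig <- function(rec, min_origin_score = 0.5) {
  d <- triage_dataset(as.data.frame(rec, stringsAsFactors = FALSE),
                      min_origin_score = min_origin_score)$decisions
  as.list(d[1, ])
}

#' Triage a screening table
#'
#' Vectorised application of [classify_contig()] plus per-rule / per-class
#' summary counts (which always sum to the number of input records).
#'
#' @param records data.frame of screening records (one per contig)
#' @param min_origin_score see [classify_contig()]
#' @return list with `decisions` (contig_id, verdict, rule_fired) and
#'   `summary` (rule x viral_class count table as a data.frame)
#' @export
triage_dataset <- function(records, min_origin_score = 0.5) {
  req <- c("contig_id", "length", "viral_class", "hallmark_count",
           "viral_gene_count", "host_gene_count", "is_provirus",
           "viral_origin_score")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$contig_id)) {
    stop("duplicate contig id(s): ",
         paste(unique(records$contig_id[duplicated(records$contig_id)]),
               collapse = ", "))
  }
  n <- nrow(records)
  if (n == 0) {
    return(list(
      decisions = data.frame(contig_id = character(0), verdict = character(0),
                             rule_fired = character(0)),
      summary = data.frame(rule_fired = TRIAGE_RULES, n = 0L)))
  }
  stopifnot(all(records$length >= 1), all(records$hallmark_count >= 0),
            all(records$viral_gene_count >= 0), all(records$host_gene_count >= 0))
  cut <- length_cutoff(records$viral_class)
  viral_denom <- pmax(records$viral_gene_count, records$hallmark_count, 1)
  ratio_ok <- records$host_gene_count / viral_denom < 1
  hall <- records$hallmark_count >= 1
  prov <- as.logical(records$is_provirus)
  screen_on <- !is.na(min_origin_score) && min_origin_score > 0

  rule <- rep("pass", n)
  rule[!prov & hall & !ratio_ok] <- "host_viral_ratio"
  rule[!hall] <- "no_hallmark"
  rule[prov & hall] <- "pass"
  rule[rule == "pass" & screen_on &
         records$viral_origin_score < min_origin_score] <- "origin_screen"
  rule[records$hallmark_count == 0 & records$host_gene_count == 0] <-
    "zero_information"
  rule[records$length < cut] <- "length_cutoff"

  decisions <- data.frame(
    contig_id = records$contig_id,
    verdict = ifelse(rule == "pass", "accepted", "rejected"),
    rule_fired = rule, stringsAsFactors = FALSE)

  tab <- table(factor(rule, levels = TRIAGE_RULES),
               factor(records$viral_class, levels = VIRAL_CLASSES))
  summary <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(summary) <- c("rule_fired", "viral_class", "n")
  list(decisions = decisions, summary = summary)
}
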