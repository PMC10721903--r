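# Sequence containers, FASTA and BLAST-outfmt-6 I/O, coverage arithmetic and
# a short-query Smith-Waterman aligner.
#
# Sequences travel as a `seq_set`: a named uppercase character vector with a
# "moltype" attribute ("dna" or "protein"). Internally simple, validated at
# the boundaries; Biostrings does the file-format heavy lifting.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
HIT_NUM_COLS <- HIT_COLS[3:12]

#' Construct a validated sequence set
#'
#' @param x named character vector of sequences (any case; stored uppercase)
#' @param moltype `"dna"`, `"protein"`, or `"auto"` to infer from content
#' @return a `seq_set`: named uppercase character vector with `moltype`
#'   attribute
#' @export
seq_set <- function(x, moltype = c("auto", "dna", "protein")) {
  moltype <- match.arg(moltype)
  x <- toupper(unlist(x))
  ids <- names(x)
  if (length(x) > 0 && (is.null(ids) || any(!nzchar(ids)))) {
    stop("all sequences must have non-empty ids")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(x))) {
    stop("empty sequence(s): ", paste(ids[!nzchar(x)], collapse = ", "))
  }
  letters_used <- unique(strsplit(paste(x, collapse = ""), "")[[1]])
  if (moltype == "auto") {
    moltype <- if (all(letters_used %in% DNA_ALPHABET)) "dna" else "protein"
  }
  alphabet <- if (moltype == "dna") DNA_ALPHABET else AA_ALPHABET
  bad <- setdiff(letters_used, alphabet)
  if (length(bad) > 0) {
    stop(sprintf("invalid %s character(s): %s", moltype,
                 paste(bad, collapse = ", ")))
  }
  structure(x, moltype = moltype, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d %s sequence(s), total %d residues\n",
              length(x), attr(x, "moltype"), sum(nchar(x))))
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  structure(NextMethod(), moltype = attr(x, "moltype"), class = "seq_set")
}

#' Read a FASTA file
#'
#' Wrapped or unwrapped multi-record FASTA; sequences are uppercased and
#' validated. Duplicate ids are an error; an empty file yields an empty set
#' with a warning.
#'
#' @param path file path (plain or gzip)
#' @param moltype `"auto"` (default), `"dna"` or `"protein"`
#' @return a [seq_set()]
#' @export
read_fasta <- function(path, moltype = c("auto", "dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not FASTA-formatted: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(structure(character(0),
                     moltype = if (moltype == "auto") "dna" else moltype,
                     class = "seq_set"))
  }
  x <- as.character(set)
  # FASTA headers: id = first whitespace-delimited token
  names(x) <- sub("\\s.*$", "", names(set))
  seq_set(x, moltype)
}

#' Write a sequence set as FASTA
#'
#' @param x a [seq_set()] or named character vector
#' @param path output path
#' @param width line-wrap width
#' @return invisibly `path`
#' @export
write_fasta <- function(x, path, width = 70L) {
  set <- Biostrings::BStringSet(unclass(x))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences (A/C/G/T/N)
#' @return character vector
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Read a tab-separated alignment hit table (BLAST outfmt-6 dialect)
#'
#' Expects 12 columns in the standard order (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) or 13 with a
#' trailing qlen. Type failures are reported with 1-based line numbers.
#'
#' @param path file path
#' @return data.frame of hits; `qlen` is `NA` when the 13th column is absent
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = FALSE)
  if (nrow(dt) == 0) return(empty_hits())
  if (!ncol(dt) %in% c(12L, 13L)) {
    stop(sprintf("expected 12 or 13 tab-separated columns, found %d in %s",
                 ncol(dt), path))
  }
  has_qlen <- ncol(dt) == 13L
  names(dt) <- c(HIT_COLS, if (has_qlen) "qlen")
  df <- as.data.frame(dt, stringsAsFactors = FALSE)
  numcols <- c(HIT_NUM_COLS, if (has_qlen) "qlen")
  for (col in numcols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column '%s' at line(s) %s of %s",
                   col, paste(head(bad, 5), collapse = ", "), path))
    }
    df[[col]] <- v
  }
  if (!has_qlen) df$qlen <- NA_real_
  validate_hits(df)
  df
}

empty_hits <- function() {
  df <- as.data.frame(setNames(rep(list(numeric(0)), 13),
                               c(HIT_COLS, "qlen")))
  df$qseqid <- character(0)
  df$sseqid <- character(0)
  df
}

validate_hits <- function(df) {
  if (any(df$qstart > df$qend)) stop("alignment hit with qstart > qend")
  if (any(df$pident < 0 | df$pident > 100)) stop("pident outside [0,100]")
  if (any(df$length < 1)) stop("alignment length < 1")
  ok <- is.na(df$qlen) | df$qlen >= df$qend
  if (!all(ok)) stop("qlen < qend in hit row(s): ",
                     paste(head(which(!ok), 5), collapse = ", "))
  invisible(df)
}

#' Write an alignment hit table (headerless outfmt-6, optional qlen column)
#' @param hits data.frame as returned by [read_hits()]
#' @param path output path
#' @return invisibly `path`
#' @export
write_hits <- function(hits, path) {
  cols <- c(HIT_COLS, if (!all(is.na(hits$qlen))) "qlen")
  data.table::fwrite(hits[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Per-HSP query coverage
#'
#' `100 * (qend - qstart + 1) / qlen`, clamped to `[0, 100]` ("qcovhsp"
#' semantics: aligned span of the best HSP over the full query length).
#'
#' @param hits data.frame with `qstart`, `qend` and optionally `qlen`
#' @param qlen optional named vector of query lengths (by `qseqid`) used where
#'   the hit rows carry no `qlen`
#' @return numeric vector of percentages
#' @export
query_coverage <- function(hits, qlen = NULL) {
  ql <- if ("qlen" %in% names(hits)) hits$qlen else rep(NA_real_, nrow(hits))
  if (any(is.na(ql))) {
    if (is.null(qlen)) {
      stop("hit rows lack qlen and no query-length lookup was supplied")
    }
    miss <- is.na(ql)
    ql[miss] <- unname(qlen[hits$qseqid[miss]])
    if (any(is.na(ql))) {
      stop("no query length for: ",
           paste(unique(hits$qseqid[is.na(ql)]), collapse = ", "))
    }
  }
  if (any(ql < 1)) stop("query length < 1")
  pmin(100, pmax(0, 100 * (hits$qend - hits$qstart + 1) / ql))
}

#' Optimal local alignment of a short query against a subject
#'
#' Smith-Waterman with per-base gap penalty (no affine opening cost). For DNA
#' both strands of the query are searched and the better hit reported; exact
#' score ties go to the hit with the lower subject start, then to the forward
#' strand. Intended for spacer/tRNA-scale queries (<= 500 residues).
#'
#' @param query,subject single named sequences ([seq_set()] of length 1 or a
#'   named character scalar)
#' @param moltype `"dna"` or `"protein"`; must match both inputs
#' @param match,mismatch,gap scoring scheme (defaults +1/-1/-2); N scores as a
#'   mismatch
#' @return one-row data.frame (AlignmentHit plus `strand`, `score`, `matches`,
#'   `gaps`) or `NULL` when no alignment scores above 0
#' @export
smith_waterman <- function(query, subject, moltype = NULL,
                           match = 1, mismatch = -1, gap = -2) {
  qid <- names(query)[1] %||% "query"
  sid <- names(subject)[1] %||% "subject"
  q <- toupper(unname(unclass(query)[1])); s <- toupper(unname(unclass(subject)[1]))
  mt <- moltype %||% attr(query, "moltype") %||%
    (if (all(strsplit(q, "")[[1]] %in% DNA_ALPHABET)) "dna" else "protein")
  mt_s <- attr(subject, "moltype")
  if (!is.null(mt_s) && !identical(mt, mt_s)) {
    stop("moltype mismatch between query (", mt, ") and subject (", mt_s, ")")
  }
  if (nchar(q) > 500) stop("query longer than 500: this aligner is for short queries")
  fwd <- .sw_align_cpp(q, s, match, mismatch, gap)
  best <- fwd; strand <- "+"
  if (mt == "dna") {
    rev <- .sw_align_cpp(revcomp(q), s, match, mismatch, gap)
    better <- rev$score > fwd$score ||
      (rev$score == fwd$score && rev$score > 0 && rev$s_start < fwd$s_start)
    if (better) { best <- rev; strand <- "-" }
  }
  if (best$score <= 0) return(NULL)
  qlen <- nchar(q)
  qs <- best$q_start; qe <- best$q_end
  if (strand == "-") { # map back to original query coordinates
    qs <- qlen - best$q_end + 1; qe <- qlen - best$q_start + 1
  }
  data.frame(
    query_id = qid, subject_id = sid,
    pident = 100 * best$matches / best$aln_len,
    length = best$aln_len, mismatch = best$mismatches,
    gapopen = best$gap_opens, gaps = best$gaps,
    qstart = qs, qend = qe, sstart = best$s_start, send = best$s_end,
    evalue = NA_real_, bitscore = best$score, qlen = qlen,
    matches = best$matches, strand = strand, score = best$score,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default pipeline configuration
#'
#' Every tunable threshold of every stage, keyed by stage, with the defaults
#' the pipeline was designed around. Serialise with [write_config()].
#'
#' @param seed integer random seed recorded into the config
#' @return nested named list
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sw = list(match = 1, mismatch = -1, gap = -2),
    triage = list(
      min_origin_score = 0.5,
      length_cutoffs = list(dsDNA = 10000, NCLDV = 10000,
                            Lavidaviridae = 10000, RNA = 1500, ssDNA = 2500)),
    network = list(
      max_evalue = 1e-5, min_bitscore = 50,
      mcl_inflation = 2, mcl_expansion = 2, mcl_prune = 1e-5,
      mcl_max_iter = 100, mcl_tol = 1e-8,
      vc_score_threshold = 1,
      species_cutoff = 95, genus_cutoff = 70),
    abundance = list(
      species = list(min_identity = 95, min_qcov = 85),
      genus = list(min_identity = 70, min_qcov = 50),
      top_n = 3),
    host = list(
      crispr = list(min_repeats = 3, repeat_len = c(19, 38),
                    spacer_len = c(19, 48), max_repeat_mismatch = 1),
      spacer_max_mismatches = 1,
      trna = list(min_aln = 60, min_identity = 97, max_mismatch = 10),
      wish = list(k = 8, pseudocount = 1, window = c(-1.30, -1.20)),
      codon_cutoff = 0.05,
      amg = list(max_evalue = 5e-5, min_identity = 50, min_qcov = 50)),
    features = list(
      integrase_keywords = c("integrase", "recombinase xerc",
                             "recombinase xerd", "site-specific recombinase"))
  )
}

#' Write / read a configuration as JSON
#' @param config nested list as from [default_config()]
#' @param path file path
#' @return `write_config`: invisibly `path`; `read_config`: the list
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
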