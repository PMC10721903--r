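# Protein hydropathy (Kyte-Doolittle GRAVY) and community lifestyle summary.

KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Kyte-Doolittle hydropathy values
#' @return named numeric vector over the 20 standard residues
#' @export
kd_table <- function() KYTE_DOOLITTLE

#' GRAVY: grand average of hydropathy
#'
#' Whole-protein mean of Kyte-Doolittle residue values; more positive is more
#' hydrophobic. `X` residues are skipped with a warning; a protein that is
#' empty or all-`X` is an error. No sliding window is applied: reported
#' per-protein indices are whole-sequence means.
#'
#' @param proteins [seq_set()] or named character vector of protein sequences
#' @return data.frame with `protein_id` and `gravy` (each within
#'   `[-4.5, 4.5]`)
#' @export
gravy <- function(proteins) {
  x <- toupper(unclass(proteins))
  if (length(x) == 0) stop("no proteins")
  ids <- names(x) %||% paste0("protein", seq_along(x))
  res <- vapply(seq_along(x), function(i) {
    aa <- strsplit(x[i], "")[[1]]
    if (length(aa) == 0) stop("empty protein: ", ids[i])
    nx <- sum(aa == "X")
    aa <- aa[aa != "X"]
    if (length(aa) == 0) stop("all-X protein: ", ids[i])
    if (nx > 0) warning(nx, " X residue(s) skipped in ", ids[i])
    vals <- KYTE_DOOLITTLE[aa]
    if (anyNA(vals)) {
      stop("non-standard residue(s) in ", ids[i], ": ",
           paste(unique(aa[is.na(vals)]), collapse = ", "))
    }
    mean(vals)
  }, numeric(1))
  data.frame(protein_id = ids, gravy = unname(res), stringsAsFactors = FALSE)
}

#' Lifestyle summary: temperate fraction of a viral community
#'
#' A virus counts as temperate when it is provirus-flagged in the screening
#' table or carries at least one ORF whose annotation matches an integrase
#' keyword (case-insensitive); each virus is counted once.
#'
#' @param screen screening table restricted to accepted viruses (needs
#'   `contig_id`, `is_provirus`)
#' @param annotations data.frame with `contig_id`, `product` (free-text gene
#'   annotation); may be empty
#' @param integrase_keywords keyword list identifying integration machinery
#' @return list with `n_viruses`, `n_temperate`, `fraction`, `temperate_ids`
#' @export
lifestyle_summary <- function(screen, annotations = NULL,
                              integrase_keywords = c(
                                "integrase", "recombinase xerc",
                                "recombinase xerd",
                                "site-specific recombinase")) {
  if (nrow(screen) == 0) stop("zero viruses")
  if (anyDuplicated(screen$contig_id)) stop("duplicate contig ids")
  temperate <- screen$contig_id[as.logical(screen$is_provirus)]
  if (!is.null(annotations) && nrow(annotations) > 0) {
    pat <- paste(integrase_keywords, collapse = "|")
    hit <- grepl(pat, annotations$product, ignore.case = TRUE)
    temperate <- union(temperate,
                       intersect(annotations$contig_id[hit],
                                 screen$contig_id))
  }
  list(n_viruses = nrow(screen), n_temperate = length(temperate),
       fraction = length(temperate) / nrow(screen),
       temperate_ids = sort(temperate))
}
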