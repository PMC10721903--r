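# Gene-sharing network: protein clusters from all-vs-all protein hits, a
# genome-level hypergeometric similarity network clustered with MCL into
# viral clusters (VCs), Jaccard comparison of VCs, VIRIDIC-style intergenomic
# similarity and ICTV-style single-linkage species/genus demarcation.

#' Filter all-vs-all protein hits into a weighted protein graph
#'
#' Keeps hits with `evalue <= max_evalue` and `bitscore >= min_bitscore`
#' (defaults 1e-5 and 50), drops self-hits, and merges reciprocal hits into
#' one undirected edge keeping the maximum bitscore as weight.
#'
#' @param hits data.frame in outfmt-6 column layout (see [read_hits()])
#' @param max_evalue,min_bitscore retention thresholds
#' @return data.frame with columns `from`, `to`, `weight`
#' @export
filter_protein_edges <- function(hits, max_evalue = 1e-5, min_bitscore = 50) {
  keep <- hits$evalue <= max_evalue & hits$bitscore >= min_bitscore &
    hits$qseqid != hits$sseqid
  h <- hits[keep, c("qseqid", "sseqid", "bitscore")]
  if (nrow(h) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0)))
  }
  a <- pmin(h$qseqid, h$sseqid)
  b <- pmax(h$qseqid, h$sseqid)
  dt <- data.table::data.table(from = a, to = b, weight = h$bitscore)
  ag <- dt[, list(weight = max(weight)), by = c("from", "to")]
  data.table::setorder(ag, from, to)
  as.data.frame(ag)
}

#' Markov clustering (MCL)
#'
#' Column-stochastic flow simulation on an undirected weighted graph with
#' self-loops (loop weight = the node's maximum incident edge weight, or 1
#' for isolated input nodes). Iterates expansion (matrix power) and inflation
#' (entrywise power + column renormalisation) with pruning of small entries
#' until the matrix change falls below `tol` or `max_iter` is reached.
#' Clusters are the connected components of the converged flow's support, so
#' every node lands in exactly one cluster.
#'
#' @param edges data.frame `from`/`to`/`weight` (as from
#'   [filter_protein_edges()]) or a symmetric adjacency matrix with dimnames
#' @param nodes optional character vector of node names to include even when
#'   isolated (each becomes its own cluster)
#' @param inflation inflation exponent (> 1; default 2)
#' @param expansion expansion power (default 2)
#' @param prune entries below this are zeroed after each step
#' @param max_iter,tol stopping controls; non-convergence returns the current
#'   clustering with `converged = FALSE` and a warning
#' @return list with `clusters` (list of character vectors, largest first),
#'   `membership` (named integer), `converged`, `iterations`
#' @export
mcl <- function(edges, nodes = NULL, inflation = 2, expansion = 2,
                prune = 1e-5, max_iter = 100, tol = 1e-8) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (is.matrix(edges) || is(edges, "Matrix")) {
    A <- methods::as(methods::as(Matrix::Matrix(edges, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    if (is.null(rownames(A))) stop("adjacency matrix needs dimnames")
    nodes <- union(nodes, rownames(A))
    A <- A[match(nodes, rownames(A)), match(nodes, rownames(A)), drop = FALSE]
    A[is.na(A)] <- 0
  } else {
    nodes <- union(nodes, unique(c(edges$from, edges$to)))
    n <- length(nodes)
    A <- Matrix::sparseMatrix(
      i = c(match(edges$from, nodes), match(edges$to, nodes)),
      j = c(match(edges$to, nodes), match(edges$from, nodes)),
      x = rep(edges$weight, 2), dims = c(n, n),
      dimnames = list(nodes, nodes), use.last.ij = FALSE)
  }
  n <- length(nodes)
  if (n == 0) {
    return(list(clusters = list(), membership = integer(0),
                converged = TRUE, iterations = 0L))
  }
  if (any(A@x < 0)) stop("negative edge weights")
  # self-loops: weight = max incident off-diagonal edge weight (or 1)
  T <- methods::as(A, "TsparseMatrix")
  off <- T@i != T@j
  loops <- numeric(n)
  if (any(off)) {
    mx <- tapply(T@x[off], T@j[off] + 1L, max)
    loops[as.integer(names(mx))] <- mx
  }
  loops[loops <= 0] <- 1
  A <- Matrix::sparseMatrix(i = c(T@i[off] + 1L, seq_len(n)),
                            j = c(T@j[off] + 1L, seq_len(n)),
                            x = c(T@x[off], loops), dims = c(n, n),
                            dimnames = list(nodes, nodes))
  M <- normalize_cols(A)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M
    for (e in seq_len(expansion - 1)) M2 <- M2 %*% M
    M2@x <- M2@x^inflation
    M2 <- Matrix::drop0(M2, tol = prune)
    M2 <- normalize_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge in ", max_iter, " iterations")
  membership <- components_from_support(M, nodes)
  cl <- split(nodes, membership)
  cl <- cl[order(-lengths(cl), vapply(cl, `[`, "", 1))]
  membership <- rep(seq_along(cl), lengths(cl))
  names(membership) <- unlist(cl)
  membership <- membership[nodes]
  list(clusters = unname(cl), membership = membership,
       converged = converged, iterations = it)
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(length(cs), 1 / cs)
}

components_from_support <- function(M, nodes) {
  # union-find over nonzero entries of the flow matrix
  n <- length(nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  M <- methods::as(M, "TsparseMatrix")
  keep <- M@x > 0
  ii <- M@i[keep] + 1L
  jj <- M@j[keep] + 1L
  for (k in seq_along(ii)) {
    ri <- find(ii[k]); rj <- find(jj[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Protein clusters (PCs) from all-vs-all protein hits
#'
#' Filters edges, runs MCL at the given inflation, and assigns every mapped
#' protein to exactly one PC (proteins without retained edges become
#' singleton PCs). PC ids are ordered by decreasing size.
#'
#' @param hits all-vs-all protein hit table
#' @param protein_genome named character vector: protein id -> genome id
#' @param max_evalue,min_bitscore see [filter_protein_edges()]
#' @param inflation,... passed to [mcl()]
#' @return data.frame with `pc_id`, `protein_id`, `genome_id`
#' @export
protein_clusters <- function(hits, protein_genome, max_evalue = 1e-5,
                             min_bitscore = 50, inflation = 2, ...) {
  edges <- filter_protein_edges(hits, max_evalue, min_bitscore)
  res <- mcl(edges, nodes = names(protein_genome), inflation = inflation, ...)
  memb <- res$membership
  pc_id <- sprintf("PC_%05d", memb)
  data.frame(pc_id = pc_id, protein_id = names(memb),
             genome_id = unname(protein_genome[names(memb)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric genome-pair similarity
#'
#' P-value of sharing at least `shared` protein clusters given genome margins
#' `pcs_a`, `pcs_b` drawn from a universe of `universe` PCs;
#' `score = -log10(pvalue * n_pairs)` (Bonferroni-style scaling by the number
#' of genome pairs, as in the vConTACT lineage). Scores can be negative.
#'
#' @param pcs_a,pcs_b number of distinct PCs of each genome
#' @param shared number of PCs shared by the pair
#' @param universe total number of distinct PCs in the analysis
#' @param n_pairs number of genome pairs considered (multiple-test scale)
#' @return data.frame with `shared`, `pvalue`, `score` (vectorised)
#' @export
hypergeometric_similarity <- function(pcs_a, pcs_b, shared, universe,
                                      n_pairs = 1) {
  if (any(universe <= 0)) stop("universe must be positive")
  if (any(shared > pmin(pcs_a, pcs_b)) || any(pmax(pcs_a, pcs_b) > universe)) {
    stop("need shared <= min(pcs_a, pcs_b) <= universe")
  }
  pvalue <- phyper(shared - 1, pcs_a, universe - pcs_a, pcs_b,
                   lower.tail = FALSE)
  data.frame(shared = shared, pvalue = pvalue,
             score = -log10(pvalue * n_pairs))
}

#' Score every genome pair sharing at least one PC
#'
#' @param pcs data.frame from [protein_clusters()]
#' @return data.frame `genome_a`, `genome_b`, `pcs_a`, `pcs_b`, `shared`,
#'   `pvalue`, `score`; attribute `genomes` lists all genomes seen
#' @export
genome_pair_scores <- function(pcs) {
  u <- unique(pcs[, c("pc_id", "genome_id")])
  genomes <- sort(unique(u$genome_id))
  pc_ids <- sort(unique(u$pc_id))
  inc <- Matrix::sparseMatrix(i = match(u$genome_id, genomes),
                              j = match(u$pc_id, pc_ids), x = 1,
                              dims = c(length(genomes), length(pc_ids)))
  shared <- Matrix::tcrossprod(inc)
  sizes <- Matrix::rowSums(inc)
  tri <- methods::as(Matrix::triu(shared, k = 1), "TsparseMatrix")
  n_pairs <- choose(length(genomes), 2)
  if (length(tri@x) == 0) {
    out <- data.frame(genome_a = character(0), genome_b = character(0),
                      pcs_a = numeric(0), pcs_b = numeric(0),
                      shared = numeric(0), pvalue = numeric(0),
                      score = numeric(0))
  } else {
    ia <- tri@i + 1L; ib <- tri@j + 1L
    hs <- hypergeometric_similarity(sizes[ia], sizes[ib], tri@x,
                                    universe = length(pc_ids),
                                    n_pairs = max(n_pairs, 1))
    out <- data.frame(genome_a = genomes[ia], genome_b = genomes[ib],
                      pcs_a = sizes[ia], pcs_b = sizes[ib],
                      shared = tri@x, pvalue = hs$pvalue, score = hs$score,
                      stringsAsFactors = FALSE)
  }
  attr(out, "genomes") <- genomes
  out
}

#' Viral clusters (VCs) from genome pair scores
#'
#' Keeps pairs with `score >= score_threshold` (default 1), clusters the
#' resulting graph with MCL (inflation 2), and calls clusters of >= 2 genomes
#' VCs; everything else is a singleton/outlier.
#'
#' @param scores data.frame from [genome_pair_scores()]
#' @param genomes character vector of all genomes under analysis (defaults to
#'   the `genomes` attribute of `scores`)
#' @param score_threshold minimum similarity score for an edge
#' @param inflation,... passed to [mcl()]
#' @return list with `vcs` (data.frame `vc_id`, `genome_id`) and `singletons`
#'   (character vector)
#' @export
build_vcs <- function(scores, genomes = attr(scores, "genomes"),
                      score_threshold = 1, inflation = 2, ...) {
  if (is.null(genomes)) genomes <- unique(c(scores$genome_a, scores$genome_b))
  keep <- is.finite(scores$score) & scores$score >= score_threshold
  edges <- data.frame(from = scores$genome_a[keep], to = scores$genome_b[keep],
                      weight = pmax(scores$score[keep], .Machine$double.eps))
  res <- mcl(edges, nodes = genomes, inflation = inflation, ...)
  sizes <- lengths(res$clusters)
  big <- which(sizes >= 2)
  vcs <- data.frame(
    vc_id = rep(sprintf("VC_%04d", seq_along(big)), sizes[big]),
    genome_id = unlist(res$clusters[big]) %||% character(0),
    stringsAsFactors = FALSE, row.names = NULL)
  singl <- sort(unlist(res$clusters[sizes < 2]))
  list(vcs = vcs, singletons = as.character(singl %||% character(0)))
}

#' Fraction of genomes outside any VC
#' @param vcs data.frame `vc_id`/`genome_id` (from [build_vcs()])
#' @param genomes all genomes under analysis
#' @return numeric fraction in `[0, 1]`
#' @export
singleton_fraction <- function(vcs, genomes) {
  if (length(genomes) == 0) stop("zero genomes")
  sum(!genomes %in% vcs$genome_id) / length(genomes)
}

#' Jaccard similarity between two VCs' PC repertoires
#' @param pcs_a,pcs_b character vectors of PC ids (the union of member
#'   genomes' PCs)
#' @return numeric in `[0, 1]`
#' @export
jaccard_vc <- function(pcs_a, pcs_b) {
  a <- unique(pcs_a); b <- unique(pcs_b)
  if (length(a) == 0 && length(b) == 0) stop("both PC sets empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' VIRIDIC-style intergenomic similarity of one genome pair
#'
#' `100 * sum(identity-weighted aligned bases) / mean(len_a, len_b)`, where
#' aligned intervals on the query genome are made non-overlapping first:
#' hits are taken in decreasing identity order and each contributes only the
#' query bases not already covered by a better hit.
#'
#' @param hits nucleotide hits with the query being genome `a` and the
#'   subject genome `b` (only `qstart`, `qend`, `pident` are used); no hits
#'   gives 0
#' @param len_a,len_b genome lengths in bp
#' @return percent similarity in `[0, 100]`
#' @export
intergenomic_similarity <- function(hits, len_a, len_b) {
  if (is.null(hits) || nrow(hits) == 0) return(0)
  if (any(hits$qend > len_a)) stop("hit extends past the query genome end")
  o <- order(-hits$pident, hits$qstart)
  covered <- logical(len_a)
  wsum <- 0
  for (k in o) {
    idx <- hits$qstart[k]:hits$qend[k]
    new <- !covered[idx]
    if (any(new)) {
      wsum <- wsum + sum(new) * hits$pident[k] / 100
      covered[idx] <- TRUE
    }
  }
  min(100, 100 * wsum / mean(c(len_a, len_b)))
}

#' All-pairs intergenomic similarity matrix
#'
#' Computes [intergenomic_similarity()] for each direction present in the hit
#' table and averages the two directions when both exist (the measure is
#' near-symmetric; averaging enforces exact symmetry). Diagonal is 100.
#'
#' @param hits nucleotide hit table with `qseqid`/`sseqid` naming genomes
#' @param lengths named vector of genome lengths
#' @return symmetric numeric matrix with 100 on the diagonal
#' @export
similarity_matrix <- function(hits, lengths) {
  g <- sort(names(lengths))
  m <- matrix(0, length(g), length(g), dimnames = list(g, g))
  diag(m) <- 100
  if (nrow(hits) > 0) {
    key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
    for (k in unique(key)) {
      h <- hits[key == k, ]
      a <- h$qseqid[1]; b <- h$sseqid[1]
      if (a == b) next
      if (!a %in% g || !b %in% g) {
        stop("hit references unknown genome: ", setdiff(c(a, b), g)[1])
      }
      m[a, b] <- intergenomic_similarity(h, lengths[a], lengths[b])
    }
    for (i in seq_along(g)) for (j in seq_len(i - 1)) {
      a <- g[i]; b <- g[j]
      vals <- c(m[a, b], m[b, a])
      v <- if (all(vals > 0)) mean(vals) else max(vals)
      m[a, b] <- v; m[b, a] <- v
    }
  }
  m
}

#' Species/genus demarcation by single linkage on intergenomic similarity
#'
#' Single-linkage clustering of `100 - similarity`; genomes joined at
#' similarity >= cutoff share a taxon. Raising a cutoff can only split
#' clusters, and because both partitions come from one tree the species
#' partition always refines the genus partition.
#'
#' @param sim symmetric similarity matrix (diagonal 100), e.g. from
#'   [similarity_matrix()]
#' @param species_cutoff,genus_cutoff demarcation thresholds (defaults 95
#'   and 70, the ICTV convention for Caudoviricetes)
#' @return list with named integer vectors `species` and `genus`
#' @export
demarcate_taxa <- function(sim, species_cutoff = 95, genus_cutoff = 70) {
  if (!isTRUE(all.equal(sim, t(sim), tolerance = 1e-8))) {
    stop("similarity matrix must be symmetric")
  }
  if (nrow(sim) == 1) {
    one <- setNames(1L, rownames(sim))
    return(list(species = one, genus = one))
  }
  tree <- hclust(as.dist(100 - sim), method = "single")
  list(species = cutree(tree, h = 100 - species_cutoff),
       genus = cutree(tree, h = 100 - genus_cutoff))
}
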