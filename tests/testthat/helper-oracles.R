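# Independent oracles used by the test suite. These deliberately take
# different computational routes from the package implementations.

# --- exhaustive local-alignment oracle --------------------------------------
# Best local alignment score as max over all start cells of a top-down
# recursive suffix alignment (memoised); independent of the bottom-up
# zero-floored DP in src/.
sw_oracle_score <- function(q, s, match = 1, mismatch = -1, gap = -2) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  m <- length(qv); n <- length(sv)
  memo <- array(NA_real_, dim = c(m + 1, n + 1))
  rec <- function(i, j) { # best extension score starting at (i, j); may stop
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- 0
    if (i <= m && j <= n) {
      sc <- if (qv[i] == sv[j]) match else mismatch
      best <- max(best, sc + rec(i + 1, j + 1))
    }
    if (i <= m) best <- max(best, gap + rec(i + 1, j))
    if (j <= n) best <- max(best, gap + rec(i, j + 1))
    memo[i, j] <<- best
    best
  }
  best_all <- 0
  for (i in seq_len(m + 1)) for (j in seq_len(n + 1)) {
    best_all <- max(best_all, rec(i, j))
  }
  best_all
}

# --- factorial hypergeometric tail oracle -----------------------------------
# P[X >= shared] by direct summation of factorial-form pmf terms.
hyper_oracle <- function(shared, a, b, universe) {
  jmax <- min(a, b)
  jmin <- max(shared, a + b - universe) # support lower bound
  if (jmin > jmax) return(if (shared > jmax) 0 else 1)
  js <- jmin:jmax
  terms <- vapply(js, function(j) {
    (factorial(a) / (factorial(j) * factorial(a - j))) *
      (factorial(universe - a) /
         (factorial(b - j) * factorial(universe - a - b + j))) /
      (factorial(universe) / (factorial(b) * factorial(universe - b)))
  }, numeric(1))
  sum(terms)
}

# --- dense reference MCL -----------------------------------------------------
# Textbook dense-matrix MCL: same loop/loop-weight conventions as the package
# but plain base-R matrices, no pruning, clusters by BFS on the converged
# support. Returns a canonical cluster representation.
mcl_reference <- function(adj, inflation = 2, expansion = 2,
                          max_iter = 200, tol = 1e-10) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  A <- adj
  diag(A) <- 0
  loops <- apply(A, 2, max)
  loops[loops <= 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M
    for (e in seq_len(expansion - 1)) M2 <- M2 %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, pmax(colSums(M2), .Machine$double.eps), "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  S <- (M > 1e-8) | t(M > 1e-8)
  visited <- rep(FALSE, n)
  clusters <- list()
  for (i in seq_len(n)) {
    if (visited[i]) next
    queue <- i; comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (visited[v]) next
      visited[v] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, which(S[v, ] & !visited))
    }
    clusters[[length(clusters) + 1L]] <- sort(nodes[comp])
  }
  canonical_clusters(clusters)
}

canonical_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, `[`, "", 1))]
}

random_graph <- function(n, p = 0.35, weighted = FALSE) {
  adj <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    if (runif(1) < p) {
      w <- if (weighted) runif(1, 0.5, 2) else 1
      adj[i, j] <- w; adj[j, i] <- w
    }
  }
  adj
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
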