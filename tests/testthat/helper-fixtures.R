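# shared fixtures and independent oracles

toy_cohort <- function(X, outcome, ids = NULL) {
  if (is.null(colnames(X))) colnames(X) <- sprintf("C%02d", seq_len(ncol(X)))
  cohort_matrix(X, outcome, ids)
}

# c disjoint bicliques with `per` patients each
make_bicliques <- function(c, per = 2L) {
  pats <- sprintf("p%03d", seq_len(c * per))
  coms <- sprintf("c%03d", seq_len(c))
  edges <- do.call(rbind, lapply(seq_len(c), function(k) {
    data.frame(patient = pats[((k - 1L) * per + 1L):(k * per)],
               comorbidity = coms[k], stringsAsFactors = FALSE)
  }))
  bipartite_from_edges(pats, coms, edges)
}

random_small_bipartite <- function(n_p, n_c, m) {
  A <- matrix(0L, n_p, n_c,
              dimnames = list(sprintf("p%d", seq_len(n_p)),
                              sprintf("c%d", seq_len(n_c))))
  A[sample.int(n_p * n_c, m)] <- 1L
  bipartite_from_edges(rownames(A), colnames(A),
                       {e <- which(A == 1L, arr.ind = TRUE)
                        data.frame(patient = rownames(A)[e[, 1L]],
                                   comorbidity = colnames(A)[e[, 2L]])})
}

# brute-force Benjamini-Hochberg step-up from the definition:
# adj_i = min_{j: p_(j) >= p_(i)} min(1, m * p_(j) / j)
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cand <- vapply(rank_i:m, function(j) min(1, m * p[ord[j]] / j), 0)
    adj[i] <- min(cand)
  }
  adj
}

# Rand index by explicit enumeration of all element pairs
ri_bruteforce <- function(a, b) {
  n <- length(a)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    total <- total + 1L
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1L
  }
  agree / total
}

# all permutations of seq_len(n) as a matrix (n! rows)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# all set partitions of seq_len(n) as label vectors
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

# Pearson chi-square from first principles (row/column margin expectations)
chisq_bruteforce <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# small cohort with explicit strata sizes for the pair (A, B):
# counts = list(ab = c(cases, controls), a_only = ..., b_only = ..., none = ...)
stratified_pair_cohort <- function(counts, extra_col = FALSE) {
  rows <- list(); outc <- integer(0)
  add <- function(xa, xb, n_case, n_ctrl) {
    k <- n_case + n_ctrl
    if (k == 0L) return()
    rows[[length(rows) + 1L]] <<- matrix(rep(c(xa, xb), k), ncol = 2, byrow = TRUE)
    outc <<- c(outc, rep(1L, n_case), rep(0L, n_ctrl))
  }
  add(1L, 1L, counts$ab[1], counts$ab[2])
  add(1L, 0L, counts$a_only[1], counts$a_only[2])
  add(0L, 1L, counts$b_only[1], counts$b_only[2])
  add(0L, 0L, counts$none[1], counts$none[2])
  X <- do.call(rbind, rows)
  colnames(X) <- c("A", "B")
  if (extra_col) {
    # third all-ones column keeps "none" patients from being zero rows
    X <- cbind(X, Z = 1L)
  }
  cohort_matrix(X, outc)
}
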