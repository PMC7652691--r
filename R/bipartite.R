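#' Build the patient-comorbidity bipartite graph
#'
#' Patient nodes are the (case, if `cases_only`) patients carrying at least
#' one of the listed comorbidities; an edge (p, c) exists iff patient p
#' carries comorbidity c. Comorbidity nodes are exactly the listed subset
#' (isolated comorbidity nodes are permitted).
#'
#' @param cohort a [cohort_matrix()].
#' @param comorbidities subset of column labels to keep as comorbidity nodes.
#' @param cases_only if TRUE (default) restrict patient nodes to cases.
#' @return An object of class `bipartite_graph`: list with `incidence`
#'   (binary patients x comorbidities matrix), `patients`, `comorbidities`,
#'   `m` (edge count).
#' @export
build_bipartite <- function(cohort, comorbidities = comorbidity_names(cohort),
                            cases_only = TRUE) {
  comorbidities <- as.character(comorbidities)
  if (length(comorbidities) == 0L) stop("empty comorbidity subset", call. = FALSE)
  if (!all(comorbidities %in% colnames(cohort$X))) {
    stop("comorbidities must be a subset of the cohort's columns", call. = FALSE)
  }
  rows <- if (cases_only) cohort$outcome == 1L else rep(TRUE, n_patients(cohort))
  A <- cohort$X[rows, comorbidities, drop = FALSE]
  A <- A[rowSums(A) >= 1L, , drop = FALSE]
  if (nrow(A) == 0L) {
    stop("no patient carries any of the listed comorbidities", call. = FALSE)
  }
  new_bipartite(A)
}

new_bipartite <- function(A) {
  stopifnot(is.matrix(A), !is.null(rownames(A)), !is.null(colnames(A)))
  storage.mode(A) <- "integer"
  structure(list(incidence = A, patients = rownames(A),
                 comorbidities = colnames(A), m = sum(A)),
            class = "bipartite_graph")
}

#' Construct a bipartite graph from an explicit edge list
#'
#' @param patients,comorbidities node label vectors.
#' @param edges two-column data.frame/matrix of (patient, comorbidity) pairs.
#' @return A `bipartite_graph`.
#' @export
bipartite_from_edges <- function(patients, comorbidities, edges) {
  A <- matrix(0L, length(patients), length(comorbidities),
              dimnames = list(as.character(patients), as.character(comorbidities)))
  if (NROW(edges) > 0) {
    pi <- match(as.character(edges[[1L]]), rownames(A))
    ci <- match(as.character(edges[[2L]]), colnames(A))
    if (anyNA(pi) || anyNA(ci)) stop("edge references unknown node", call. = FALSE)
    A[cbind(pi, ci)] <- 1L
  }
  new_bipartite(A)
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("<bipartite_graph> %d patients x %d comorbidities, %d edges\n",
              length(x$patients), length(x$comorbidities), x$m))
  invisible(x)
}

# community_of: named integer vector over c(patients, comorbidities)
split_assignment <- function(graph, community_of) {
  nodes <- c(graph$patients, graph$comorbidities)
  if (!all(nodes %in% names(community_of))) {
    stop("community_of must cover every node", call. = FALSE)
  }
  list(pat = unname(community_of[graph$patients]),
       com = unname(community_of[graph$comorbidities]))
}

#' Barber bipartite modularity
#'
#' `Q_B = (1/m) * sum_{i,j} (A_ij - k_i d_j / m) * delta(g_i, g_j)` over
#' patient-comorbidity node pairs, where `k_i`, `d_j` are node degrees and
#' `delta` compares community labels. Lies in `[-1, 1]`; the all-in-one
#' partition scores exactly 0.
#'
#' @param graph a `bipartite_graph` with at least one edge.
#' @param community_of named integer vector mapping every node (patients and
#'   comorbidities) to a community index.
#' @return The modularity value.
#' @export
barber_modularity <- function(graph, community_of) {
  if (graph$m == 0L) stop("modularity undefined on an edgeless graph", call. = FALSE)
  asg <- split_assignment(graph, community_of)
  A <- graph$incidence
  k <- rowSums(A); d <- colSums(A); m <- graph$m
  comms <- union(asg$pat, asg$com)
  q <- 0
  for (cm in comms) {
    pi <- asg$pat == cm; ci <- asg$com == cm
    if (!any(pi) || !any(ci)) next
    e_c <- sum(A[pi, ci, drop = FALSE])
    q <- q + e_c / m - (sum(k[pi]) * sum(d[ci])) / m^2
  }
  q
}

brim_once <- function(B, m, init_com, max_iter = 200L) {
  # Alternating exact reassignment given the other side fixed. Two spare
  # (initially empty) community slots give any node whose best populated
  # community scores negative a zero-contribution escape, so fixed points
  # can shed nodes into fresh communities; each half-step is Q-monotone.
  slots <- max(init_com) + 2L
  n_p <- nrow(B); n_c <- ncol(B)
  com <- init_com
  q_prev <- -Inf
  pat <- rep(1L, n_p); q <- 0
  for (it in seq_len(max_iter)) {
    Mc <- matrix(0, n_c, slots); Mc[cbind(seq_len(n_c), com)] <- 1
    Sp <- B %*% Mc
    pat <- max.col(Sp, ties.method = "first")
    Mp <- matrix(0, n_p, slots); Mp[cbind(seq_len(n_p), pat)] <- 1
    Sc <- crossprod(B, Mp)
    com <- max.col(Sc, ties.method = "first")
    q <- sum(Sc[cbind(seq_len(n_c), com)]) / m
    if (q <= q_prev + 1e-12) break
    q_prev <- q
  }
  list(pat = pat, com = com, q = max(q_prev, q))
}

#' Find biclusters by Barber modularity maximization (BRIM)
#'
#' Alternating two-mode reassignment: with comorbidity assignments fixed,
#' every patient moves to the community maximizing its modularity
#' contribution (ties broken toward the lowest community index); roles then
#' swap; iteration continues to a fixed point. The optimization restarts from
#' `restarts` seeded random comorbidity assignments for every initial
#' community count in `1..max_communities`, and returns the best partition
#' found (ties: fewer communities, then lexicographically smallest canonical
#' assignment). Degree-zero nodes are excluded from the optimization and
#' appended as singleton communities. Deterministic given `seed`.
#'
#' @param graph a `bipartite_graph`.
#' @param seed integer seed.
#' @param restarts random restarts per community count (default 20).
#' @param max_communities upper bound of the initial community-count sweep;
#'   defaults to the number of connected comorbidity nodes.
#' @return An object of class `bicluster_partition`: list with
#'   `community_of` (named integer vector over all nodes, indices contiguous
#'   from 0), `n_communities`, and `q` (the Barber modularity of the
#'   partition).
#' @export
find_biclusters <- function(graph, seed = 1L, restarts = 20L,
                            max_communities = NULL) {
  A <- graph$incidence
  k <- rowSums(A); d <- colSums(A)
  act_p <- which(k > 0); act_c <- which(d > 0)
  if (length(act_c) == 0L) {
    # edgeless graph: all nodes isolated singletons, Q defined as 0
    nodes <- c(graph$patients, graph$comorbidities)
    co <- setNames(seq_along(nodes) - 1L, nodes)
    return(structure(list(community_of = co, n_communities = length(nodes), q = 0),
                     class = "bicluster_partition"))
  }
  Aa <- A[act_p, act_c, drop = FALSE]
  m <- sum(Aa)
  B <- Aa - outer(rowSums(Aa), colSums(Aa)) / m
  cmax <- if (is.null(max_communities)) length(act_c) else
    min(max_communities, length(act_c))
  best <- NULL
  withr::with_seed(seed, {
    for (cc in seq_len(cmax)) {
      for (r in seq_len(restarts)) {
        # restart 1 is a deterministic round-robin spread (all-singletons
        # when cc equals the comorbidity count); the rest are random
        init <- if (r == 1L) rep_len(seq_len(cc), length(act_c)) else
          sample.int(cc, length(act_c), replace = TRUE)
        fit <- brim_once(B, m, init)
        cand <- canonicalize_fit(fit$pat, fit$com)
        if (is.null(best) || better_partition(fit$q, cand, best)) {
          best <- list(q = fit$q, pat = cand$pat, com = cand$com,
                       n = cand$n, key = cand$key)
        }
        if (cc == 1L) break  # single-community start is deterministic
      }
    }
  })
  assemble_partition(graph, act_p, act_c, best)
}

canonicalize_fit <- function(pat, com) {
  joint <- c(pat, com)
  relab <- match(joint, unique(joint)) - 1L
  pat2 <- relab[seq_along(pat)]
  com2 <- relab[length(pat) + seq_along(com)]
  list(pat = pat2, com = com2, n = length(unique(relab)),
       key = paste(sprintf("%04d", relab), collapse = ","))
}

better_partition <- function(q, cand, best) {
  if (q > best$q + 1e-10) return(TRUE)
  if (q < best$q - 1e-10) return(FALSE)
  if (cand$n != best$n) return(cand$n < best$n)
  cand$key < best$key
}

assemble_partition <- function(graph, act_p, act_c, best) {
  n_p <- length(graph$patients); n_c <- length(graph$comorbidities)
  pat_full <- rep(NA_integer_, n_p); com_full <- rep(NA_integer_, n_c)
  pat_full[act_p] <- best$pat
  com_full[act_c] <- best$com
  # isolated nodes become singleton communities after the optimized ones
  nxt <- best$n
  for (i in which(is.na(pat_full))) { pat_full[i] <- nxt; nxt <- nxt + 1L }
  for (i in which(is.na(com_full))) { com_full[i] <- nxt; nxt <- nxt + 1L }
  co <- setNames(c(pat_full, com_full), c(graph$patients, graph$comorbidities))
  structure(list(community_of = co, n_communities = nxt,
                 q = barber_modularity(graph, co)),
            class = "bicluster_partition")
}

#' @export
print.bicluster_partition <- function(x, ...) {
  cat(sprintf("<bicluster_partition> %d communities, Q_B = %.4f\n",
              x$n_communities, x$q))
  invisible(x)
}

#' Exhaustive Barber-modularity optimum (small graphs)
#'
#' Independent reference optimizer: enumerates every partition of the
#' connected comorbidity nodes (set partitions) and, for each, assigns every
#' patient to its exactly-optimal community (or leaves it alone when every
#' community contribution is negative), which yields the global optimum
#' because the objective only involves cross-type co-membership. Exponential
#' in the number of comorbidity nodes; intended for graphs with <= ~8
#' comorbidities.
#'
#' @param graph a `bipartite_graph` with an edge.
#' @return List with `q` (optimal modularity).
#' @export
exhaustive_modularity_optimum <- function(graph) {
  A <- graph$incidence
  d <- colSums(A)
  act_c <- which(d > 0)
  act_p <- which(rowSums(A) > 0)
  Aa <- A[act_p, act_c, drop = FALSE]
  m <- sum(Aa)
  B <- Aa - outer(rowSums(Aa), colSums(Aa)) / m
  n_c <- length(act_c)
  best_q <- -Inf
  for (part in set_partitions(n_c)) {
    cmax <- max(part)
    Mc <- matrix(0, n_c, cmax); Mc[cbind(seq_len(n_c), part)] <- 1
    Sp <- B %*% Mc
    contrib <- apply(Sp, 1L, max)
    q <- (sum(pmax(contrib, 0))) / m  # patient alone contributes 0
    if (q > best_q) best_q <- q
  }
  list(q = best_q)
}

# all set partitions of 1..n as integer label vectors (restricted growth)
set_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

#' Random bipartite graph with identical size and density
#'
#' Uniform sample of `m` distinct edges over the full patient x comorbidity
#' grid; node sets are unchanged and degree sequences are not preserved.
#'
#' @param graph a `bipartite_graph`.
#' @param seed integer seed.
#' @return A `bipartite_graph` with the same node sets and edge count.
#' @export
random_bipartite_same_density <- function(graph, seed = 1L) {
  n_p <- length(graph$patients); n_c <- length(graph$comorbidities)
  A <- matrix(0L, n_p, n_c, dimnames = list(graph$patients, graph$comorbidities))
  cells <- withr::with_seed(seed, sample.int(n_p * n_c, graph$m))
  A[cells] <- 1L
  new_bipartite(A)
}

#' Permutation significance of the bicluster modularity
#'
#' Draws `n_permutations` random graphs of identical size and density
#' ([random_bipartite_same_density()]), re-optimizes each with
#' [find_biclusters()], and compares the observed maximized modularity
#' against the permuted maxima using the `(r + 1) / (R + 1)` convention, so
#' the minimum attainable p with 1000 permutations is < .001.
#'
#' @param graph a `bipartite_graph`.
#' @param q_observed observed modularity (a number or a
#'   `bicluster_partition`).
#' @param n_permutations number of random graphs (default 1000).
#' @param seed integer seed (per-permutation seeds are derived from it).
#' @param restarts restarts passed to the inner optimizer.
#' @param max_communities community-count cap passed to the inner optimizer;
#'   when used, the observed modularity should come from an equally capped
#'   [find_biclusters()] run so the comparison stays exchangeable.
#' @return Class `modularity_significance`: list with `q_observed`,
#'   `random_mean`, `random_sd`, `n_permutations`, `p_value`.
#' @export
modularity_significance <- function(graph, q_observed, n_permutations = 1000L,
                                    seed = 1L, restarts = 20L,
                                    max_communities = NULL) {
  stopifnot(n_permutations >= 1L)
  if (inherits(q_observed, "bicluster_partition")) q_observed <- q_observed$q
  sub <- derive_seeds(seed, 2L * n_permutations)
  qs <- vapply(seq_len(n_permutations), function(i) {
    g <- random_bipartite_same_density(graph, seed = sub[2L * i - 1L])
    find_biclusters(g, seed = sub[2L * i], restarts = restarts,
                    max_communities = max_communities)$q
  }, 0)
  structure(list(q_observed = q_observed,
                 random_mean = mean(qs),
                 random_sd = stats::sd(qs),
                 n_permutations = n_permutations,
                 p_value = (1 + sum(qs >= q_observed - 1e-12)) / (n_permutations + 1)),
            class = "modularity_significance")
}

# deterministic stream of sub-seeds below 2^31
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @export
print.modularity_significance <- function(x, ...) {
  cat(sprintf("<modularity_significance> Q = %.3f; random mean %.3f (sd %.3f); P = %.4g (%d permutations)\n",
              x$q_observed, x$random_mean, x$random_sd, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Export/import a bipartite graph as an edge-list TSV
#'
#' @param graph a `bipartite_graph`.
#' @param path TSV path (`patient<TAB>comorbidity` with header).
#' @return `path` / a `bipartite_graph`.
#' @export
write_bipartite_tsv <- function(graph, path) {
  e <- which(graph$incidence == 1L, arr.ind = TRUE)
  df <- data.frame(patient = graph$patients[e[, 1L]],
                   comorbidity = graph$comorbidities[e[, 2L]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$patient, df$comorbidity), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bipartite_tsv
#' @param patients,comorbidities optional full node lists (to preserve
#'   isolated nodes that carry no edge).
#' @export
read_bipartite_tsv <- function(path, patients = NULL, comorbidities = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (is.null(patients)) patients <- sort(unique(df$patient))
  if (is.null(comorbidities)) comorbidities <- sort(unique(df$comorbidity))
  bipartite_from_edges(patients, comorbidities, df)
}

#' Write/read a partition as a two-column TSV (node, community)
#'
#' @param partition a `bicluster_partition` (or named community vector).
#' @param path TSV path.
#' @return `path` / named integer vector.
#' @export
write_partition_tsv <- function(partition, path) {
  co <- if (inherits(partition, "bicluster_partition")) partition$community_of else partition
  utils::write.table(data.frame(node = names(co), community = unname(co),
                                stringsAsFactors = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  setNames(as.integer(df$community), df$node)
}
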