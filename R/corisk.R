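#' Build the integrated co-occurrence risk (CoRisk) network
#'
#' Superimposes the directed comorbidity risk network derived from the
#' replicated pairwise results onto the patient-comorbidity bipartite
#' bicluster network. Each significant replicated directionality sub-test
#' contributes one directed risk edge; the arrow points toward the
#' comorbidity against which the pair adds significant risk alone: when
#' "(A&B) vs B" is significant the arrow runs from A to B (the pair is
#' riskier than B alone), so a pattern of `both` yields two opposing arrows.
#'
#' @param bipartite a [build_bipartite()] graph.
#' @param partition a [find_biclusters()] partition of that graph.
#' @param replicated a [replicate_pairs()] result; its comorbidities must be
#'   nodes of `bipartite`.
#' @param single_or optional named vector/mapping of single-comorbidity odds
#'   ratios to attach to comorbidity nodes (e.g. from
#'   [single_comorbidity_or()]).
#' @return An object of class `corisk_network`: list with `bipartite`,
#'   `partition`, `risk_edges` (data.frame `source`, `target`, `or_pair`,
#'   `significant_direction`), `node_or`, `patient_class` (filled by
#'   [classify_inner_outer()]), `coordinates` (filled by
#'   [explode_layout()]).
#' @export
build_corisk <- function(bipartite, partition, replicated, single_or = NULL) {
  stopifnot(inherits(bipartite, "bipartite_graph"),
            inherits(partition, "bicluster_partition"),
            inherits(replicated, "replicated_pair_set"))
  pr <- replicated$pairs
  missing <- setdiff(replicated$unique_comorbidities, bipartite$comorbidities)
  if (length(missing) > 0L) {
    stop(sprintf("replicated pair references comorbidities absent from the network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  edges <- list()
  or_col <- if ("or.train" %in% names(pr)) "or.train" else "or"
  for (r in seq_len(nrow(pr))) {
    a <- pr$comorbidity_a[r]; b <- pr$comorbidity_b[r]
    orv <- if (or_col %in% names(pr)) pr[[or_col]][r] else NA_real_
    dp <- pr$direction_pattern[r]
    if (dp %in% c("both", "b_only")) {  # (A&B) vs B significant: arrow A -> B
      edges[[length(edges) + 1L]] <- data.frame(
        source = a, target = b, or_pair = orv,
        significant_direction = "ab_vs_b", stringsAsFactors = FALSE)
    }
    if (dp %in% c("both", "a_only")) {  # (A&B) vs A significant: arrow B -> A
      edges[[length(edges) + 1L]] <- data.frame(
        source = b, target = a, or_pair = orv,
        significant_direction = "ab_vs_a", stringsAsFactors = FALSE)
    }
  }
  risk_edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               or_pair = numeric(0), significant_direction = character(0),
               stringsAsFactors = FALSE)
  node_or <- rep(NA_real_, length(bipartite$comorbidities))
  names(node_or) <- bipartite$comorbidities
  if (!is.null(single_or)) {
    if (is.data.frame(single_or)) single_or <- setNames(single_or$or, single_or$comorbidity)
    shared <- intersect(names(single_or), names(node_or))
    node_or[shared] <- single_or[shared]
  }
  net <- structure(list(bipartite = bipartite, partition = partition,
                        risk_edges = risk_edges, node_or = node_or,
                        patient_class = NULL, coordinates = NULL),
                   class = "corisk_network")
  net$patient_class <- classify_inner_outer(net)$patient_class
  net
}

#' @export
print.corisk_network <- function(x, ...) {
  cat(sprintf("<corisk_network> %d patients, %d comorbidities, %d bipartite edges, %d risk edges, %d biclusters\n",
              length(x$bipartite$patients), length(x$bipartite$comorbidities),
              x$bipartite$m, nrow(x$risk_edges), x$partition$n_communities))
  invisible(x)
}

#' Classify inner/outer patients and tally them per bicluster
#'
#' A patient connected to exactly one comorbidity sits on the outer side of
#' its bicluster; a patient with more than one comorbidity is inner. The
#' counts table has one column per bicluster (communities containing at
#' least one patient) and two rows: patients with exactly one vs more than
#' one comorbidity.
#'
#' @param network a `corisk_network` (or a list with `bipartite` and
#'   `partition`).
#' @return List with `patient_class` (named vector, `"outer"`/`"inner"`) and
#'   `counts` (2 x C integer matrix, rows `single`/`multi`, columns named by
#'   community index).
#' @export
classify_inner_outer <- function(network) {
  g <- network$bipartite
  deg <- rowSums(g$incidence)
  cls <- ifelse(deg > 1L, "inner", "outer")
  names(cls) <- g$patients
  comm <- network$partition$community_of[g$patients]
  lev <- sort(unique(comm))
  counts <- rbind(single = vapply(lev, function(cm) sum(cls == "outer" & comm == cm), 0L),
                  multi = vapply(lev, function(cm) sum(cls == "inner" & comm == cm), 0L))
  colnames(counts) <- as.character(lev)
  list(patient_class = cls, counts = counts)
}

#' Chi-square test of bicluster heterogeneity
#'
#' Pearson chi-square (no continuity correction) on the 2 x C table of
#' patients with exactly one vs more than one comorbidity per bicluster;
#' expected counts come from the row/column margins and df = C - 1.
#'
#' @param counts 2 x C matrix of non-negative counts with no zero column.
#' @return Class `heterogeneity_result`: list with `counts`, `chi2`, `df`,
#'   `p_value`, `n`.
#' @export
heterogeneity_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("counts must be a 2 x C table", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(colSums(counts) == 0) || any(rowSums(counts) == 0)) {
    stop("zero margin in heterogeneity table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(counts = counts,
                 chi2 = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value,
                 n = sum(counts)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity_result> X2(%d) = %.1f, N = %d, P = %.3g\n",
              x$df, x$chi2, x$n, x$p_value))
  invisible(x)
}

#' Inner/outer counts formatted with percentages
#'
#' @param counts 2 x C matrix from [classify_inner_outer()].
#' @param labels optional column labels (e.g. dominant comorbidity names).
#' @return data.frame with per-bicluster single/multi counts, percentages
#'   (2 decimals) and totals, plus a `Total` row margin column.
#' @export
inner_outer_table <- function(counts, labels = colnames(counts)) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  df <- data.frame(bicluster = labels,
                   single = counts[1L, ], multi = counts[2L, ], total = tot,
                   pct_single = round(100 * counts[1L, ] / tot, 2),
                   pct_multi = round(100 * counts[2L, ] / tot, 2),
                   stringsAsFactors = FALSE, row.names = NULL)
  df[nrow(df) + 1L, ] <- list("Total", sum(counts[1L, ]), sum(counts[2L, ]),
                              sum(tot), round(100 * sum(counts[1L, ]) / sum(tot), 2),
                              round(100 * sum(counts[2L, ]) / sum(tot), 2))
  df
}

#' Detect asymmetrical risk hubs
#'
#' A comorbidity whose directed risk-edge in-degree exceeds its out-degree
#' is an asymmetrical hub: the implicated pairs add significant risk
#' relative to it alone. Returned sorted by (in - out) descending.
#'
#' @param network a `corisk_network`.
#' @return data.frame `comorbidity`, `in_degree`, `out_degree`.
#' @export
detect_asymmetric_hubs <- function(network) {
  re <- network$risk_edges
  nodes <- network$bipartite$comorbidities
  ind <- vapply(nodes, function(x) sum(re$target == x), 0L)
  outd <- vapply(nodes, function(x) sum(re$source == x), 0L)
  keep <- ind > outd
  df <- data.frame(comorbidity = nodes[keep], in_degree = ind[keep],
                   out_degree = outd[keep], stringsAsFactors = FALSE,
                   row.names = NULL)
  df[order(-(df$in_degree - df$out_degree), df$comorbidity), , drop = FALSE]
}

#' Exploded bicluster layout
#'
#' Computes a seeded Fruchterman-Reingold base layout of the bipartite graph
#' and then translates every community rigidly along the unit vector from
#' the global centroid to the community centroid by
#' `explode_factor * layout radius` (radius = largest node distance from the
#' global centroid). Pure translation per community, so within-community
#' distances are preserved exactly; a factor of 0 returns the base layout.
#'
#' @param network a `corisk_network` (or list with `bipartite` and
#'   `partition`).
#' @param explode_factor non-negative displacement factor.
#' @param seed integer seed for the base layout.
#' @return Numeric matrix (nodes x 2) with rownames over all nodes.
#' @export
explode_layout <- function(network, explode_factor = 0.5, seed = 1L) {
  stopifnot(explode_factor >= 0)
  g <- network$bipartite
  ig <- igraph_from_bipartite(g)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(ig, niter = 500))
  rownames(xy) <- igraph::V(ig)$name
  comm <- network$partition$community_of[rownames(xy)]
  centre <- colMeans(xy)
  radius <- max(sqrt(colSums((t(xy) - centre)^2)), 1e-9)
  for (cm in unique(comm)) {
    rows <- which(comm == cm)
    cen <- colMeans(xy[rows, , drop = FALSE])
    v <- cen - centre
    len <- sqrt(sum(v^2))
    if (len < 1e-12) next
    xy[rows, ] <- xy[rows, ] + rep(v / len * explode_factor * radius,
                                   each = length(rows))
  }
  colnames(xy) <- c("x", "y")
  xy
}

igraph_from_bipartite <- function(g) {
  e <- which(g$incidence == 1L, arr.ind = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = g$patients[e[, 1L]], to = g$comorbidities[e[, 2L]],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = c(g$patients, g$comorbidities),
                          type = c(rep(FALSE, length(g$patients)),
                                   rep(TRUE, length(g$comorbidities))),
                          stringsAsFactors = FALSE))
}

corisk_igraph <- function(network) {
  g <- network$bipartite
  e <- which(g$incidence == 1L, arr.ind = TRUE)
  bip <- data.frame(from = g$patients[e[, 1L]], to = g$comorbidities[e[, 2L]],
                    kind = "bipartite", or_pair = NA_real_,
                    direction = NA_character_, stringsAsFactors = FALSE)
  re <- network$risk_edges
  risk <- if (nrow(re) > 0) data.frame(from = re$source, to = re$target,
                                       kind = "risk", or_pair = re$or_pair,
                                       direction = re$significant_direction,
                                       stringsAsFactors = FALSE) else bip[0, ]
  nodes <- c(g$patients, g$comorbidities)
  co <- network$partition$community_of[nodes]
  pc <- rep(NA_character_, length(nodes)); names(pc) <- nodes
  if (!is.null(network$patient_class)) {
    pc[names(network$patient_class)] <- network$patient_class
  }
  orv <- rep(NA_real_, length(nodes)); names(orv) <- nodes
  orv[names(network$node_or)] <- network$node_or
  vdf <- data.frame(name = nodes,
                    type = c(rep("patient", length(g$patients)),
                             rep("comorbidity", length(g$comorbidities))),
                    community = unname(co), or = unname(orv),
                    patient_class = unname(pc), stringsAsFactors = FALSE)
  if (!is.null(network$coordinates)) {
    vdf$x <- network$coordinates[nodes, "x"]
    vdf$y <- network$coordinates[nodes, "y"]
  }
  igraph::graph_from_data_frame(rbind(bip, risk), directed = TRUE,
                                vertices = vdf)
}

#' Export / import a CoRisk network
#'
#' GraphML carries node attributes (`type`, `community`, `or`,
#' `patient_class` and, when a layout is present, `x`, `y`) and edge
#' attributes (`kind` in bipartite/risk, `or_pair`, `direction`); bipartite
#' edges are stored once, patient to comorbidity, and are undirected in
#' meaning. The JSON file mirrors the same schema. [import_network()]
#' reconstructs a `corisk_network` from either format.
#'
#' @param network a `corisk_network`.
#' @param format `"graphml"` or `"json"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, format = c("graphml", "json"), path) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- corisk_igraph(network)
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    g <- network$bipartite
    e <- which(g$incidence == 1L, arr.ind = TRUE)
    obj <- list(
      patients = g$patients,
      comorbidities = g$comorbidities,
      bipartite_edges = data.frame(patient = g$patients[e[, 1L]],
                                   comorbidity = g$comorbidities[e[, 2L]],
                                   stringsAsFactors = FALSE),
      risk_edges = network$risk_edges,
      community_of = as.list(network$partition$community_of),
      q = network$partition$q,
      node_or = as.list(network$node_or),
      patient_class = as.list(network$patient_class),
      coordinates = if (is.null(network$coordinates)) NULL else
        data.frame(node = rownames(network$coordinates),
                   x = network$coordinates[, "x"],
                   y = network$coordinates[, "y"],
                   stringsAsFactors = FALSE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    vdf <- igraph::as_data_frame(ig, what = "vertices")
    edf <- igraph::as_data_frame(ig, what = "edges")
    pats <- vdf$name[vdf$type == "patient"]
    coms <- vdf$name[vdf$type == "comorbidity"]
    bip <- edf[edf$kind == "bipartite", , drop = FALSE]
    g <- bipartite_from_edges(pats, coms, bip[, c("from", "to")])
    co <- setNames(as.integer(vdf$community), vdf$name)
    part <- structure(list(community_of = co[c(pats, coms)],
                           n_communities = length(unique(co)),
                           q = if (g$m > 0) barber_modularity(g, co) else 0),
                      class = "bicluster_partition")
    risk <- edf[edf$kind == "risk", , drop = FALSE]
    risk_edges <- data.frame(source = risk$from, target = risk$to,
                             or_pair = as.numeric(risk$or_pair),
                             significant_direction = as.character(risk$direction),
                             stringsAsFactors = FALSE)
    node_or <- setNames(as.numeric(vdf$or[match(coms, vdf$name)]), coms)
    pc <- setNames(as.character(vdf$patient_class[match(pats, vdf$name)]), pats)
    coords <- NULL
    if (all(c("x", "y") %in% names(vdf))) {
      coords <- cbind(x = as.numeric(vdf$x), y = as.numeric(vdf$y))
      rownames(coords) <- vdf$name
      coords <- coords[c(pats, coms), , drop = FALSE]
    }
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    g <- bipartite_from_edges(obj$patients, obj$comorbidities,
                              obj$bipartite_edges)
    co <- unlist(obj$community_of)
    part <- structure(list(community_of = co[c(g$patients, g$comorbidities)],
                           n_communities = length(unique(co)),
                           q = obj$q),
                      class = "bicluster_partition")
    risk_edges <- as.data.frame(obj$risk_edges, stringsAsFactors = FALSE)
    if (nrow(risk_edges) == 0) {
      risk_edges <- data.frame(source = character(0), target = character(0),
                               or_pair = numeric(0),
                               significant_direction = character(0),
                               stringsAsFactors = FALSE)
    }
    node_or <- unlist(obj$node_or)
    pc <- unlist(obj$patient_class)
    coords <- NULL
    if (!is.null(obj$coordinates) && NROW(obj$coordinates) > 0) {
      coords <- cbind(x = obj$coordinates$x, y = obj$coordinates$y)
      rownames(coords) <- obj$coordinates$node
    }
  }
  structure(list(bipartite = g, partition = part, risk_edges = risk_edges,
                 node_or = node_or, patient_class = pc, coordinates = coords),
            class = "corisk_network")
}
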