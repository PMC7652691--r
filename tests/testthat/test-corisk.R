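# small fixture: 2-comorbidity network with a replicated pair set
corisk_fixture <- function(pattern = "both") {
  X <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 0L))
  colnames(X) <- c("A", "B")
  ch <- cohort_matrix(X, rep(1, 5))
  g <- build_bipartite(ch, c("A", "B"))
  part <- find_biclusters(g, seed = 1)
  rs <- structure(list(
    pairs = data.frame(comorbidity_a = "A", comorbidity_b = "B",
                       direction_pattern = pattern, or.train = 2.5,
                       stringsAsFactors = FALSE),
    unique_comorbidities = c("A", "B")), class = "replicated_pair_set")
  build_corisk(g, part, rs, single_or = c(A = 1.4, B = 1.9))
}

test_that("risk edges follow the directionality-pattern arrow semantics", {
  both <- corisk_fixture("both")
  expect_identical(nrow(both$risk_edges), 2L)
  expect_setequal(paste(both$risk_edges$source, both$risk_edges$target),
                  c("A B", "B A"))

  # a_only: (A&B) vs A significant -> pair riskier than A alone -> arrow B->A
  aonly <- corisk_fixture("a_only")
  expect_identical(nrow(aonly$risk_edges), 1L)
  expect_identical(aonly$risk_edges$source, "B")
  expect_identical(aonly$risk_edges$target, "A")
  expect_identical(aonly$risk_edges$significant_direction, "ab_vs_a")
  expect_equal(aonly$risk_edges$or_pair, 2.5)

  bonly <- corisk_fixture("b_only")
  expect_identical(bonly$risk_edges$source, "A")
  expect_identical(bonly$risk_edges$target, "B")

  empty <- structure(list(pairs = data.frame(), unique_comorbidities = character(0)),
                     class = "replicated_pair_set")
  net0 <- build_corisk(corisk_fixture()$bipartite, corisk_fixture()$partition, empty)
  expect_identical(nrow(net0$risk_edges), 0L)

  badset <- structure(list(
    pairs = data.frame(comorbidity_a = "A", comorbidity_b = "Z",
                       direction_pattern = "both", stringsAsFactors = FALSE),
    unique_comorbidities = c("A", "Z")), class = "replicated_pair_set")
  expect_error(build_corisk(corisk_fixture()$bipartite,
                            corisk_fixture()$partition, badset), "absent")
})

test_that("inner/outer classification tallies patients by bipartite degree", {
  net <- corisk_fixture()
  io <- classify_inner_outer(net)
  deg <- rowSums(net$bipartite$incidence)
  expect_identical(unname(io$patient_class[deg == 1]),
                   rep("outer", sum(deg == 1)))
  expect_identical(unname(io$patient_class[deg > 1]),
                   rep("inner", sum(deg > 1)))
  expect_identical(sum(io$counts), length(net$bipartite$patients))
  # column totals equal bicluster patient totals
  comm <- net$partition$community_of[net$bipartite$patients]
  expect_identical(as.integer(colSums(io$counts)),
                   unname(as.integer(table(comm)[colnames(io$counts)])))

  # 5 outer + 3 inner in one cluster
  X <- rbind(matrix(c(1L, 0L), 5, 2, byrow = TRUE),
             matrix(c(1L, 1L), 3, 2, byrow = TRUE))
  colnames(X) <- c("A", "B")
  ch <- cohort_matrix(X, rep(1, 8))
  g <- build_bipartite(ch, c("A", "B"))
  one <- structure(list(community_of = setNames(rep(0L, 10),
                                                c(g$patients, g$comorbidities)),
                        n_communities = 1L, q = 0),
                   class = "bicluster_partition")
  io2 <- classify_inner_outer(list(bipartite = g, partition = one))
  expect_identical(unname(io2$counts[, "0"]), c(5L, 3L))
})

test_that("heterogeneity chi-square matches first-principles computation", {
  expect_equal(heterogeneity_chi_square(rbind(c(10, 10), c(10, 10)))$chi2, 0)
  expect_identical(heterogeneity_chi_square(rbind(c(10, 10), c(10, 10)))$df, 1L)

  prop <- rbind(c(10, 20, 30), c(20, 40, 60))  # proportional columns
  expect_equal(heterogeneity_chi_square(prop)$chi2, 0)

  set.seed(31)
  for (i in 1:15) {
    tab <- matrix(rpois(2 * 4, 30) + 1, 2, 4)
    got <- heterogeneity_chi_square(tab)
    expect_equal(got$chi2, chisq_bruteforce(tab))
    expect_identical(got$df, 3L)
    expect_identical(got$n, sum(tab))
  }
  expect_error(heterogeneity_chi_square(rbind(c(0, 5), c(0, 5))), "zero margin")
  expect_error(heterogeneity_chi_square(matrix(1, 3, 3)), "2 x C")
})

test_that("asymmetric hubs are the nodes with in-degree above out-degree", {
  net <- corisk_fixture("a_only")  # single arrow B -> A
  hubs <- detect_asymmetric_hubs(net)
  expect_identical(hubs$comorbidity, "A")
  expect_identical(hubs$in_degree, 1L)

  # symmetric two-node cycle: no hub
  expect_identical(nrow(detect_asymmetric_hubs(corisk_fixture("both"))), 0L)

  # star of arrows into one node
  X <- matrix(1L, 4, 6, dimnames = list(NULL, sprintf("C%d", 1:6)))
  ch <- cohort_matrix(X, rep(1, 4))
  g <- build_bipartite(ch)
  part <- find_biclusters(g, seed = 1)
  rs <- structure(list(
    pairs = data.frame(comorbidity_a = sprintf("C%d", 2:6), comorbidity_b = "C1",
                       direction_pattern = "b_only", or.train = 2,
                       stringsAsFactors = FALSE),
    unique_comorbidities = sprintf("C%d", 1:6)), class = "replicated_pair_set")
  net2 <- build_corisk(g, part, rs)
  hubs2 <- detect_asymmetric_hubs(net2)
  expect_identical(hubs2$comorbidity, "C1")
  expect_identical(hubs2$in_degree, 5L)
  expect_identical(hubs2$out_degree, 0L)
})

test_that("exploded layout translates communities rigidly and monotonically", {
  set.seed(71)
  X <- rbind(matrix(rbinom(40, 1, c(0.9, 0.9, 0.05, 0.05)), 10, 4, byrow = TRUE),
             matrix(rbinom(40, 1, c(0.05, 0.05, 0.9, 0.9)), 10, 4, byrow = TRUE))
  X[rowSums(X) == 0, 1] <- 1L
  colnames(X) <- sprintf("C%d", 1:4)
  ch <- cohort_matrix(X, rep(1, 20))
  g <- build_bipartite(ch)
  part <- find_biclusters(g, seed = 2)
  empty <- structure(list(pairs = data.frame(), unique_comorbidities = character(0)),
                     class = "replicated_pair_set")
  net <- build_corisk(g, part, empty)

  base <- explode_layout(net, explode_factor = 0, seed = 5)
  expect_identical(base, explode_layout(net, explode_factor = 0, seed = 5))

  ex1 <- explode_layout(net, explode_factor = 0.5, seed = 5)
  ex2 <- explode_layout(net, explode_factor = 1.5, seed = 5)

  # within-community pairwise distances are preserved exactly
  comm <- part$community_of[rownames(base)]
  for (cm in unique(comm)) {
    nodes <- names(comm)[comm == cm]
    if (length(nodes) < 2) next
    expect_equal(as.matrix(dist(ex1[nodes, ])),
                 as.matrix(dist(base[nodes, ])), tolerance = 1e-9)
  }

  # centroid separation grows with the factor (when > 1 community)
  cen_dist <- function(xy) {
    cms <- unique(comm)
    if (length(cms) < 2) return(NA_real_)
    cent <- t(vapply(cms, function(cm)
      colMeans(xy[names(comm)[comm == cm], , drop = FALSE]), c(0, 0)))
    min(dist(cent))
  }
  if (length(unique(comm)) > 1) {
    expect_gte(cen_dist(ex2), cen_dist(ex1) - 1e-9)
    expect_gte(cen_dist(ex1), cen_dist(base) - 1e-9)
  }
})

test_that("network export round-trips through GraphML and JSON", {
  net <- corisk_fixture("both")
  net$coordinates <- explode_layout(net, 0.5, seed = 1)
  for (fmt in c("graphml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(net, fmt, f)
    back <- import_network(f, fmt)
    expect_setequal(back$bipartite$patients, net$bipartite$patients)
    expect_identical(back$bipartite$incidence[net$bipartite$patients,
                                              net$bipartite$comorbidities],
                     net$bipartite$incidence)
    expect_equal(sort(paste(back$risk_edges$source, back$risk_edges$target)),
                 sort(paste(net$risk_edges$source, net$risk_edges$target)))
    expect_equal(back$partition$community_of[names(net$partition$community_of)],
                 net$partition$community_of)
    expect_equal(back$node_or[names(net$node_or)], net$node_or)
    expect_identical(back$patient_class[names(net$patient_class)],
                     net$patient_class)
    expect_equal(back$coordinates[rownames(net$coordinates), ],
                 net$coordinates, tolerance = 1e-9)
  }

  # no risk edges still yields a valid file
  empty <- structure(list(pairs = data.frame(), unique_comorbidities = character(0)),
                     class = "replicated_pair_set")
  net0 <- build_corisk(net$bipartite, net$partition, empty)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net0, "graphml", f)
  expect_identical(nrow(import_network(f, "graphml")$risk_edges), 0L)

  expect_error(export_network(net, "dot", tempfile()), "arg")
})
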