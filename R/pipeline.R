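#' Build a pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Each cohort entry is either `list(path = "<csv>")` or
#' `list(synth = <spec>)` where `<spec>` is a [synth_config()], or a list
#' with `preset: "medicare-like"` plus overrides (`n_cases`, `n_controls`,
#' `seed`), or the full set of [synth_config()] fields (`blocks` given as in
#' `block_spec`, planted pairs as a list of `list(a, b, log_or)`).
#'
#' @param training,replication cohort sources (see above).
#' @param alpha significance level on adjusted p-values.
#' @param prevalence_threshold low-prevalence filter threshold.
#' @param prevalence_mode `"individual"` or `"combined"`.
#' @param biclustering list: `seed`, `restarts`, `n_permutations`.
#' @param ri list: `n_permutations`, `seed`.
#' @param layout list: `factor`, `seed`.
#' @param out_dir output directory (created if missing).
#' @return Class `pipeline_config` list.
#' @export
pipeline_config <- function(training, replication,
                            alpha = 0.05,
                            prevalence_threshold = 0.01,
                            prevalence_mode = c("individual", "combined"),
                            biclustering = list(),
                            ri = list(),
                            layout = list(),
                            out_dir = tempfile("corisknet-run-")) {
  prevalence_mode <- match.arg(prevalence_mode)
  stopifnot(alpha > 0, alpha < 1,
            prevalence_threshold > 0, prevalence_threshold < 1)
  bic <- utils::modifyList(list(seed = 1L, restarts = 20L,
                                n_permutations = 1000L,
                                max_communities = NULL), biclustering)
  ri <- utils::modifyList(list(seed = 1L, n_permutations = 1000L), ri)
  layout <- utils::modifyList(list(factor = 0.5, seed = 1L), layout)
  structure(list(training = normalize_cohort_source(training, "training"),
                 replication = normalize_cohort_source(replication, "replication"),
                 alpha = alpha,
                 prevalence_threshold = prevalence_threshold,
                 prevalence_mode = prevalence_mode,
                 biclustering = bic, ri = ri, layout = layout,
                 out_dir = out_dir),
            class = "pipeline_config")
}

normalize_cohort_source <- function(src, which) {
  if (inherits(src, "synth_config")) src <- list(synth = src)
  if (inherits(src, "cohort_matrix")) src <- list(cohort = src)
  if (is.character(src) && length(src) == 1L) src <- list(path = src)
  has <- c(!is.null(src$path), !is.null(src$synth), !is.null(src$cohort))
  if (sum(has) != 1L) {
    stop(sprintf("%s cohort: provide exactly one of path / synth / cohort", which),
         call. = FALSE)
  }
  if (!is.null(src$synth) && !inherits(src$synth, "synth_config")) {
    src$synth <- synth_config_from_list(src$synth)
  }
  src
}

synth_config_from_list <- function(sp) {
  if (!is.null(sp$preset)) {
    if (!identical(sp$preset, "medicare-like")) {
      stop(sprintf("unknown synth preset '%s'", sp$preset), call. = FALSE)
    }
    args <- sp[names(sp) %in% c("n_cases", "n_controls", "seed")]
    return(do.call(synth_config_medicare_like, args))
  }
  K <- length(sp$comorbidity_names)
  G <- matrix(0, K, K, dimnames = list(sp$comorbidity_names, sp$comorbidity_names))
  for (p in sp$pairs %||% list()) {
    G[p$a, p$b] <- p$log_or
    G[p$b, p$a] <- p$log_or
  }
  synth_config(n_cases = sp$n_cases,
               n_controls = sp$n_controls %||% sp$n_cases,
               comorbidity_names = sp$comorbidity_names,
               block_spec = sp$blocks %||% list(),
               p_out = sp$p_out %||% 0.05,
               pair_log_or = G,
               main_effects = sp$main_effects %||% 0,
               intercept = sp$intercept %||% 0,
               seed = sp$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

load_or_simulate <- function(src, out_dir, label) {
  if (!is.null(src$cohort)) {
    return(list(cohort = src$cohort, truth = NULL))
  }
  if (!is.null(src$path)) {
    return(list(cohort = read_cohort(src$path), truth = NULL))
  }
  gen <- generate_cohort(src$synth)
  write_cohort(gen$cohort, file.path(out_dir, paste0("cohort_", label, ".csv")))
  write_truth(gen$truth, file.path(out_dir, paste0("truth_", label, ".json")))
  gen
}

run_rq1 <- function(cohort, config, counts) {
  c1 <- filter_zero_comorbidity_patients(cohort)
  counts$after_zero_filter <- n_patients(c1)
  fl <- filter_low_prevalence(c1, config$prevalence_threshold,
                              config$prevalence_mode)
  counts$after_prevalence_filter <- n_patients(fl$cohort)
  counts$comorbidities_removed <- length(fl$removed)
  overall <- pairwise_overall_test(fl$cohort, config$alpha)
  directed <- pairwise_directionality_test(fl$cohort, overall, config$alpha)
  list(cohort = fl$cohort, removed = fl$removed, pairs = directed,
       counts = counts)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: load or simulate the training and
#' replication cohorts; remove zero-comorbidity patients and low-prevalence
#' comorbidities; pairwise overall and directionality risk tests with FDR;
#' cross-dataset replication; bipartite bicluster networks of the replicated
#' comorbidities (cases only) with permutation significance of the
#' modularity; Rand-index comparison of the two comorbidity partitions;
#' CoRisk network with inner/outer classification, bicluster-heterogeneity
#' chi-square, asymmetric-hub detection and exploded layout; file exports
#' and a run report. Identical configuration (all seeds included) yields
#' identical outputs.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return The run report (list), invisibly; all result files are written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(alpha = config$alpha,
                 prevalence_threshold = config$prevalence_threshold,
                 prevalence_mode = config$prevalence_mode,
                 seeds = list(biclustering = config$biclustering$seed,
                              ri = config$ri$seed,
                              layout = config$layout$seed),
                 stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    report$stages[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    val
  }

  train <- stage("load_training", load_or_simulate(config$training, out_dir, "training"))
  repl <- stage("load_replication", load_or_simulate(config$replication, out_dir, "replication"))
  report$counts <- list(training = list(input = n_patients(train$cohort)),
                        replication = list(input = n_patients(repl$cohort)))

  rq1_tr <- stage("risk_training",
                  run_rq1(train$cohort, config, report$counts$training))
  rq1_rp <- stage("risk_replication",
                  run_rq1(repl$cohort, config, report$counts$replication))
  report$counts$training <- rq1_tr$counts
  report$counts$replication <- rq1_rp$counts

  repset <- stage("replication_matching", replicate_pairs(rq1_tr$pairs, rq1_rp$pairs))
  report$n_significant_training <- sum(rq1_tr$pairs$significant_overall)
  report$n_replicated_pairs <- nrow(repset$pairs)
  report$replicated_comorbidities <- repset$unique_comorbidities

  tab1 <- rq1_tr$pairs
  key <- paste(pmin(tab1$comorbidity_a, tab1$comorbidity_b),
               pmax(tab1$comorbidity_a, tab1$comorbidity_b))
  rkey <- paste(repset$pairs$comorbidity_a, repset$pairs$comorbidity_b)
  tab1$replicated <- key %in% rkey
  utils::write.table(tab1, file.path(out_dir, "pairwise_risk_training.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(rq1_rp$pairs, file.path(out_dir, "pairwise_risk_replication.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  if (nrow(repset$pairs) == 0L) {
    report$note <- "no replicated significant pairs; network stages skipped"
    report$elapsed <- round(proc.time()[["elapsed"]] - t0, 3)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(report))
  }

  nets <- list()
  for (lab in c("training", "replication")) {
    rq1 <- if (lab == "training") rq1_tr else rq1_rp
    g <- stage(paste0("bipartite_", lab),
               build_bipartite(rq1$cohort, repset$unique_comorbidities,
                               cases_only = TRUE))
    part <- stage(paste0("biclusters_", lab),
                  find_biclusters(g, seed = config$biclustering$seed,
                                  restarts = config$biclustering$restarts,
                                  max_communities = config$biclustering$max_communities))
    sig <- stage(paste0("modularity_significance_", lab),
                 modularity_significance(g, part,
                                         n_permutations = config$biclustering$n_permutations,
                                         seed = config$biclustering$seed,
                                         restarts = config$biclustering$restarts,
                                         max_communities = config$biclustering$max_communities))
    write_partition_tsv(part, file.path(out_dir, paste0("partition_", lab, ".tsv")))
    jsonlite::write_json(unclass(sig),
                         file.path(out_dir, paste0("modularity_", lab, ".json")),
                         auto_unbox = TRUE, digits = NA)
    report[[paste0("modularity_", lab)]] <-
      list(q = part$q, n_biclusters = comorbidity_community_count(g, part),
           p_value = sig$p_value, random_mean = sig$random_mean,
           random_sd = sig$random_sd)
    nets[[lab]] <- list(graph = g, partition = part)
  }

  ri <- stage("rand_index", {
    la <- nets$training$partition$community_of[repset$unique_comorbidities]
    lb <- nets$replication$partition$community_of[repset$unique_comorbidities]
    ri_significance(la, lb, n_permutations = config$ri$n_permutations,
                    seed = config$ri$seed)
  })
  jsonlite::write_json(unclass(ri), file.path(out_dir, "rand_index.json"),
                       auto_unbox = TRUE, digits = NA)
  report$rand_index <- list(ri = ri$ri, p_value = ri$p_value,
                            random_mean = ri$random_mean)

  corisk <- stage("corisk", {
    so <- single_comorbidity_or(rq1_tr$cohort, config$alpha)
    build_corisk(nets$training$graph, nets$training$partition, repset,
                 single_or = so)
  })
  io <- stage("inner_outer", classify_inner_outer(corisk))
  het <- stage("heterogeneity", heterogeneity_chi_square(io$counts))
  report$heterogeneity <- list(chi2 = het$chi2, df = het$df,
                               p_value = het$p_value, n = het$n)
  utils::write.table(inner_outer_table(io$counts),
                     file.path(out_dir, "inner_outer_counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  hubs <- stage("asymmetric_hubs", detect_asymmetric_hubs(corisk))
  report$asymmetric_hubs <- hubs$comorbidity
  corisk$coordinates <- stage("layout",
                              explode_layout(corisk, config$layout$factor,
                                             config$layout$seed))
  stage("export", {
    export_network(corisk, "graphml", file.path(out_dir, "corisk.graphml"))
    export_network(corisk, "json", file.path(out_dir, "corisk.json"))
  })
  report$elapsed <- round(proc.time()[["elapsed"]] - t0, 3)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}

comorbidity_community_count <- function(graph, partition) {
  length(unique(partition$community_of[graph$comorbidities]))
}

#' Published bicluster patient tallies (hip-fracture readmission cohort)
#'
#' The published 2 x 7 table of readmitted hip-fracture patients carrying
#' exactly one vs more than one high-risk comorbidity across the seven
#' patient-comorbidity biclusters of a Medicare training network (N = 6150).
#' Shipped as a plain-text reference table; used to validate
#' [heterogeneity_chi_square()] and [inner_outer_table()] against the
#' published statistic.
#'
#' @return 2 x 7 integer matrix (rows `single`, `multi`; columns named by
#'   the bicluster's dominant comorbidity).
#' @export
hfx_bicluster_counts <- function() {
  path <- system.file("extdata", "hfx_bicluster_counts.tsv",
                      package = "corisknet", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, c("single_comorbidity", "multi_comorbidity")]))
  dimnames(m) <- list(c("single", "multi"), df$bicluster)
  m
}
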