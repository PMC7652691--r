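#' Remove patients carrying none of the comorbidities
#'
#' @param cohort a [cohort_matrix()].
#' @return A `cohort_matrix` retaining only patients with at least one
#'   comorbidity, order preserved (possibly empty).
#' @export
filter_zero_comorbidity_patients <- function(cohort) {
  keep <- rowSums(cohort$X) >= 1L
  subset_cohort(cohort, patients = keep)
}

#' Remove low-prevalence comorbidities
#'
#' Drops rare comorbidity columns and then any patient whose row sum falls to
#' zero. Two modes: `"individual"` (default) removes every comorbidity whose
#' own prevalence is below `threshold`; `"combined"` removes the largest
#' ascending-prevalence set of comorbidities whose union still covers less
#' than `threshold` of the patients (the literal reading of "together
#' occurred in less than 1%").
#'
#' @param cohort a non-empty [cohort_matrix()].
#' @param threshold prevalence threshold in (0, 1); default 0.01.
#' @param mode `"individual"` or `"combined"`.
#' @return A list with `cohort` (filtered) and `removed` (labels of dropped
#'   comorbidities, sorted by prevalence ascending).
#' @export
filter_low_prevalence <- function(cohort, threshold = 0.01,
                                  mode = c("individual", "combined")) {
  mode <- match.arg(mode)
  if (n_patients(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  prev <- colMeans(cohort$X)
  if (mode == "individual") {
    removed <- names(prev)[prev < threshold]
  } else {
    ord <- order(prev, seq_along(prev))
    removed <- character(0)
    covered <- rep(FALSE, n_patients(cohort))
    for (j in ord) {
      cand <- covered | (cohort$X[, j] == 1L)
      if (mean(cand) < threshold) {
        covered <- cand
        removed <- c(removed, names(prev)[j])
      } else break
    }
  }
  removed <- removed[order(prev[removed], removed)]
  keep_cols <- setdiff(colnames(cohort$X), removed)
  if (length(keep_cols) == 0L) {
    stop("low-prevalence filter would remove every comorbidity", call. = FALSE)
  }
  out <- subset_cohort(cohort, comorbidities = keep_cols)
  out <- filter_zero_comorbidity_patients(out)
  list(cohort = out, removed = removed)
}

#' Odds ratio with Woolf confidence interval and Fisher exact p-value
#'
#' For the 2x2 table (`a` exposed cases, `b` exposed controls, `c` unexposed
#' cases, `d` unexposed controls) computes the cross-product odds ratio
#' `a*d / (b*c)`. When any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe) before computing the OR and CI. The CI is the Woolf
#' logit interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` on the
#' (possibly corrected) cells; the p-value is the two-sided Fisher exact
#' probability on the uncorrected counts.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param alpha two-sided CI level complement (default 0.05 for a 95% CI).
#' @return A list (class `or_result`) with `or`, `ci_low`, `ci_high`,
#'   `p_raw`, and `p_fdr` (NA until adjusted within a test family).
#' @export
odds_ratio_ci <- function(a, b, c, d, alpha = 0.05) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || sum(cells) == 0) {
    stop("cell counts must be non-negative with positive total", call. = FALSE)
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("undefined odds ratio: degenerate 2x2 margin", call. = FALSE)
  }
  cc <- if (any(cells == 0)) cells + 0.5 else cells
  or <- (cc[1L] * cc[4L]) / (cc[2L] * cc[3L])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - alpha / 2)
  p <- stats::fisher.test(matrix(cells, 2L, 2L, byrow = TRUE))$p.value
  p <- min(max(p, 0), 1)  # guard against numerical overshoot of the exact sum
  structure(list(or = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 p_raw = p, p_fdr = NA_real_),
            class = "or_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

pair_counts <- function(cohort) {
  case <- cohort$outcome == 1L
  Xc <- cohort$X[case, , drop = FALSE]
  Xk <- cohort$X[!case, , drop = FALSE]
  list(co_case = crossprod(Xc), co_ctrl = crossprod(Xk),
       marg_case = colSums(Xc), marg_ctrl = colSums(Xk),
       n_case = nrow(Xc), n_ctrl = nrow(Xk))
}

#' Pairwise overall risk test
#'
#' For every unordered comorbidity pair (A, B): exposure = carrying both A
#' and B, reference = all other patients, outcome = case vs control. Each
#' pair gets a cross-product OR, Woolf 95% CI and two-sided Fisher exact
#' p-value ([odds_ratio_ci()]); Benjamini-Hochberg adjustment is applied over
#' the full family of testable pairs. Pairs with a degenerate margin (e.g.
#' nobody carries both) are returned with `testable = FALSE` and excluded
#' from the FDR family.
#'
#' @param cohort a [cohort_matrix()] with >= 2 comorbidities and both outcome
#'   classes present.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return A data.frame with one row per pair: `comorbidity_a`,
#'   `comorbidity_b`, `or`, `ci_low`, `ci_high`, `p_raw`, `p_fdr`,
#'   `testable`, `significant_overall`.
#' @export
pairwise_overall_test <- function(cohort, alpha = 0.05) {
  K <- ncol(cohort$X)
  if (K < 2L) stop("need at least 2 comorbidities", call. = FALSE)
  if (length(unique(cohort$outcome)) < 2L) {
    stop("cohort must contain both cases and controls", call. = FALSE)
  }
  pc <- pair_counts(cohort)
  idx <- which(upper.tri(diag(K)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  nm <- colnames(cohort$X)
  res <- data.frame(comorbidity_a = nm[idx[, 1L]],
                    comorbidity_b = nm[idx[, 2L]],
                    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p_raw = NA_real_, p_fdr = NA_real_,
                    testable = TRUE, significant_overall = FALSE,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    a <- pc$co_case[i, j]; b <- pc$co_ctrl[i, j]
    cc <- pc$n_case - a;   d <- pc$n_ctrl - b
    or <- tryCatch(odds_ratio_ci(a, b, cc, d, alpha), error = function(e) NULL)
    if (is.null(or)) {
      res$testable[r] <- FALSE
    } else {
      res$or[r] <- or$or; res$ci_low[r] <- or$ci_low
      res$ci_high[r] <- or$ci_high; res$p_raw[r] <- or$p_raw
    }
  }
  t <- res$testable
  res$p_fdr[t] <- bh_adjust(res$p_raw[t])
  res$significant_overall[t] <- res$p_fdr[t] < alpha
  attr(res, "alpha") <- alpha
  res
}

dir_test_one <- function(pc, i, j, other) {
  # exposure = A&B; reference = carrier of `other`'s partner only
  a <- pc$co_case[i, j]; b <- pc$co_ctrl[i, j]
  ref_case <- pc$marg_case[other] - a
  ref_ctrl <- pc$marg_ctrl[other] - b
  if ((ref_case + ref_ctrl) == 0) return(NULL)
  tryCatch(odds_ratio_ci(a, b, ref_case, ref_ctrl), error = function(e) NULL)
}

#' Pairwise directionality test
#'
#' For each overall-significant pair, two disjoint-stratum tests establish
#' which member the added risk is relative to: test (1) contrasts patients
#' with A and B against patients with A and not B; test (2) contrasts A and B
#' against B and not A. FDR correction is applied separately within the
#' test-(1) family and within the test-(2) family. `direction_pattern`
#' records which sub-tests are significant: `both`, `a_only` ((A&B) vs A
#' only), `b_only`, or `neither`; untestable sub-tests (empty reference
#' stratum) count as not significant and are flagged.
#'
#' @param cohort the [cohort_matrix()] the overall test was run on.
#' @param pairs result of [pairwise_overall_test()]; only rows with
#'   `significant_overall` are tested.
#' @param alpha significance level on adjusted p-values.
#' @return `pairs` with added columns `ab_vs_a_or`, `ab_vs_a_ci_low`,
#'   `ab_vs_a_ci_high`, `ab_vs_a_p_raw`, `ab_vs_a_p_fdr`,
#'   `ab_vs_a_testable` (and the `ab_vs_b_*` counterparts) and
#'   `direction_pattern`.
#' @export
pairwise_directionality_test <- function(cohort, pairs, alpha = 0.05) {
  pc <- pair_counts(cohort)
  nm <- colnames(cohort$X)
  for (side in c("ab_vs_a", "ab_vs_b")) {
    for (f in c("or", "ci_low", "ci_high", "p_raw", "p_fdr")) {
      pairs[[paste0(side, "_", f)]] <- NA_real_
    }
    pairs[[paste0(side, "_testable")]] <- NA
  }
  pairs$direction_pattern <- NA_character_
  sig <- which(pairs$significant_overall)
  for (r in sig) {
    i <- match(pairs$comorbidity_a[r], nm)
    j <- match(pairs$comorbidity_b[r], nm)
    for (side in c("ab_vs_a", "ab_vs_b")) {
      other <- if (side == "ab_vs_a") i else j
      or <- dir_test_one(pc, i, j, other)
      pairs[[paste0(side, "_testable")]][r] <- !is.null(or)
      if (!is.null(or)) {
        pairs[[paste0(side, "_or")]][r] <- or$or
        pairs[[paste0(side, "_ci_low")]][r] <- or$ci_low
        pairs[[paste0(side, "_ci_high")]][r] <- or$ci_high
        pairs[[paste0(side, "_p_raw")]][r] <- or$p_raw
      }
    }
  }
  for (side in c("ab_vs_a", "ab_vs_b")) {
    t <- which(!is.na(pairs[[paste0(side, "_p_raw")]]))
    pairs[[paste0(side, "_p_fdr")]][t] <- bh_adjust(pairs[[paste0(side, "_p_raw")]][t])
  }
  sa <- !is.na(pairs$ab_vs_a_p_fdr) & pairs$ab_vs_a_p_fdr < alpha
  sb <- !is.na(pairs$ab_vs_b_p_fdr) & pairs$ab_vs_b_p_fdr < alpha
  pat <- ifelse(sa & sb, "both",
         ifelse(sa, "a_only", ifelse(sb, "b_only", "neither")))
  pairs$direction_pattern[sig] <- pat[sig]
  pairs
}

canonical_pair_frame <- function(pairs) {
  swap <- pairs$comorbidity_a > pairs$comorbidity_b
  if (any(swap)) {
    tmp <- pairs$comorbidity_a[swap]
    pairs$comorbidity_a[swap] <- pairs$comorbidity_b[swap]
    pairs$comorbidity_b[swap] <- tmp
    if ("direction_pattern" %in% names(pairs)) {
      dp <- pairs$direction_pattern[swap]
      pairs$direction_pattern[swap] <-
        ifelse(dp == "a_only", "b_only", ifelse(dp == "b_only", "a_only", dp))
    }
    for (f in c("or", "ci_low", "ci_high", "p_raw", "p_fdr", "testable")) {
      ca <- paste0("ab_vs_a_", f); cb <- paste0("ab_vs_b_", f)
      if (all(c(ca, cb) %in% names(pairs))) {
        tmp <- pairs[[ca]][swap]
        pairs[[ca]][swap] <- pairs[[cb]][swap]
        pairs[[cb]][swap] <- tmp
      }
    }
  }
  pairs
}

#' Cross-dataset replication of significant directed pairs
#'
#' Retains pairs that are overall-significant in both the training and the
#' replication results and whose direction pattern is identical and not
#' `neither`. Pair orientation is canonicalized by label order, so the two
#' result sets may list members in either order.
#'
#' @param train,repl results of [pairwise_directionality_test()] on the
#'   training and replication cohorts (same alpha).
#' @return A list (class `replicated_pair_set`) with `pairs` (merged
#'   data.frame, training columns suffixed `.train`, replication `.repl`,
#'   shared `direction_pattern`) and `unique_comorbidities` (sorted union of
#'   member labels).
#' @export
replicate_pairs <- function(train, repl) {
  tr <- canonical_pair_frame(train)
  rp <- canonical_pair_frame(repl)
  key <- function(d) paste(d$comorbidity_a, d$comorbidity_b, sep = "\r")
  tr_sig <- tr[tr$significant_overall & !is.na(tr$direction_pattern) &
                 tr$direction_pattern != "neither", , drop = FALSE]
  rp_sig <- rp[rp$significant_overall & !is.na(rp$direction_pattern) &
                 rp$direction_pattern != "neither", , drop = FALSE]
  m <- match(key(tr_sig), key(rp_sig))
  keep <- !is.na(m) & tr_sig$direction_pattern == rp_sig$direction_pattern[m]
  tr_keep <- tr_sig[keep, , drop = FALSE]
  rp_keep <- rp_sig[m[keep], , drop = FALSE]
  merged <- data.frame(comorbidity_a = tr_keep$comorbidity_a,
                       comorbidity_b = tr_keep$comorbidity_b,
                       direction_pattern = tr_keep$direction_pattern,
                       stringsAsFactors = FALSE)
  for (f in setdiff(names(tr_keep), c("comorbidity_a", "comorbidity_b",
                                      "direction_pattern"))) {
    merged[[paste0(f, ".train")]] <- tr_keep[[f]]
    merged[[paste0(f, ".repl")]] <- rp_keep[[f]]
  }
  rownames(merged) <- NULL
  structure(list(pairs = merged,
                 unique_comorbidities = sort(unique(c(merged$comorbidity_a,
                                                      merged$comorbidity_b)))),
            class = "replicated_pair_set")
}

#' @export
print.replicated_pair_set <- function(x, ...) {
  cat(sprintf("<replicated_pair_set> %d replicated pairs over %d comorbidities\n",
              nrow(x$pairs), length(x$unique_comorbidities)))
  invisible(x)
}

#' Single-comorbidity odds ratios
#'
#' Convenience for annotating network nodes: the case-control OR of each
#' individual comorbidity (carrier vs non-carrier), with Woolf CI and Fisher
#' p, FDR-adjusted over the comorbidity family.
#'
#' @param cohort a [cohort_matrix()].
#' @param alpha significance level on adjusted p-values.
#' @return data.frame with `comorbidity`, `or`, `ci_low`, `ci_high`,
#'   `p_raw`, `p_fdr`, `significant`.
#' @export
single_comorbidity_or <- function(cohort, alpha = 0.05) {
  pc <- pair_counts(cohort)
  nm <- colnames(cohort$X)
  rows <- lapply(seq_along(nm), function(i) {
    a <- pc$marg_case[i]; b <- pc$marg_ctrl[i]
    or <- tryCatch(odds_ratio_ci(a, b, pc$n_case - a, pc$n_ctrl - b),
                   error = function(e) NULL)
    if (is.null(or)) return(data.frame(comorbidity = nm[i], or = NA_real_,
                                       ci_low = NA_real_, ci_high = NA_real_,
                                       p_raw = NA_real_, stringsAsFactors = FALSE))
    data.frame(comorbidity = nm[i], or = or$or, ci_low = or$ci_low,
               ci_high = or$ci_high, p_raw = or$p_raw, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  t <- !is.na(res$p_raw)
  res$p_fdr <- NA_real_
  res$p_fdr[t] <- bh_adjust(res$p_raw[t])
  res$significant <- !is.na(res$p_fdr) & res$p_fdr < alpha
  res
}
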