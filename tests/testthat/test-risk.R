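test_that("zero-comorbidity filter keeps exactly the carriers", {
  X <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 1L))
  colnames(X) <- c("A", "B")
  ch <- cohort_matrix(X, c(1, 0, 1))
  expect_identical(n_patients(filter_zero_comorbidity_patients(ch)), 2L)
  expect_identical(filter_zero_comorbidity_patients(ch)$patient_ids,
                   ch$patient_ids[2:3])

  allzero <- cohort_matrix(matrix(0L, 3, 2, dimnames = list(NULL, c("A", "B"))),
                           c(1, 0, 1))
  expect_identical(n_patients(filter_zero_comorbidity_patients(allzero)), 0L)

  nz <- cohort_matrix(matrix(1L, 3, 2, dimnames = list(NULL, c("A", "B"))),
                      c(1, 0, 1))
  expect_identical(filter_zero_comorbidity_patients(nz), nz)
})

test_that("low-prevalence filter removes rare columns then emptied patients", {
  set.seed(1)
  X <- matrix(0L, 1000, 3, dimnames = list(NULL, c("common", "rare", "mid")))
  X[, "common"] <- 1L
  X[1:5, "rare"] <- 1L
  X[1:500, "mid"] <- 1L
  ch <- cohort_matrix(X, rep(c(1, 0), 500))
  fl <- filter_low_prevalence(ch, 0.01)
  expect_identical(fl$removed, "rare")
  expect_identical(colnames(fl$cohort$X), c("common", "mid"))
  expect_identical(n_patients(fl$cohort), 1000L)

  # identity when everything is common enough
  fl2 <- filter_low_prevalence(ch, 0.001)
  expect_identical(fl2$cohort, ch)
  expect_length(fl2$removed, 0L)

  # a patient whose only comorbidity is removed disappears too
  X2 <- rbind(c(1L, 0L), matrix(c(0L, 1L), 999, 2, byrow = TRUE))
  colnames(X2) <- c("rare", "common")
  ch2 <- cohort_matrix(X2, rep(c(1, 0), 500))
  fl3 <- filter_low_prevalence(ch2, 0.01)
  expect_identical(n_patients(fl3$cohort), 999L)
  expect_false("P000001" %in% fl3$cohort$patient_ids)
  # oracle: recomputed row sums after the column drop are all positive
  expect_true(all(rowSums(fl3$cohort$X) >= 1))

  expect_error(filter_low_prevalence(ch, 0), "threshold")
  expect_error(filter_low_prevalence(ch, 1), "threshold")
})

test_that("combined prevalence mode removes the rare set by union coverage", {
  # rare1 in 4/1000, rare2 in 5/1000 (disjoint): union 0.9% < 1% -> both go;
  # mid at 2% stays because adding it would push the union over threshold
  X <- matrix(0L, 1000, 4,
              dimnames = list(NULL, c("common", "rare1", "rare2", "mid")))
  X[, "common"] <- 1L
  X[1:4, "rare1"] <- 1L
  X[5:9, "rare2"] <- 1L
  X[10:29, "mid"] <- 1L
  ch <- cohort_matrix(X, rep(c(1, 0), 500))
  fl <- filter_low_prevalence(ch, 0.01, mode = "combined")
  expect_setequal(fl$removed, c("rare1", "rare2"))
  # removed labels come back sorted by prevalence ascending
  expect_identical(fl$removed, c("rare1", "rare2"))
  expect_true("mid" %in% colnames(fl$cohort$X))
})

test_that("odds_ratio_ci matches hand-computed cross-product and Woolf CI", {
  o <- odds_ratio_ci(10, 5, 5, 10)
  expect_equal(o$or, 4.0)
  expect_equal(o$ci_low, exp(log(4) - qnorm(0.975) * sqrt(0.6)), tolerance = 1e-10)
  expect_equal(o$ci_high, exp(log(4) + qnorm(0.975) * sqrt(0.6)), tolerance = 1e-10)
  expect_equal(o$ci_low, 0.876, tolerance = 1e-3)
  expect_equal(o$ci_high, 18.26, tolerance = 1e-3)
  expect_equal(o$p_raw, fisher.test(matrix(c(10, 5, 5, 10), 2, 2))$p.value)

  # zero cell: Haldane-Anscombe 0.5 on every cell
  oz <- odds_ratio_ci(5, 0, 5, 10)
  expect_equal(oz$or, (5.5 * 10.5) / (0.5 * 5.5))
  expect_equal(oz$ci_low,
               exp(log(oz$or) - qnorm(0.975) * sqrt(1/5.5 + 1/0.5 + 1/5.5 + 1/10.5)),
               tolerance = 1e-10)

  expect_error(odds_ratio_ci(0, 0, 3, 4), "degenerate")
  expect_error(odds_ratio_ci(0, 3, 0, 4), "degenerate")
})

test_that("odds_ratio_ci is invariant under joint row/column transposition", {
  set.seed(5)
  for (i in 1:20) {
    cells <- rpois(4, 8)
    if ((cells[1] + cells[2]) == 0 || (cells[3] + cells[4]) == 0 ||
        (cells[1] + cells[3]) == 0 || (cells[2] + cells[4]) == 0) next
    o1 <- odds_ratio_ci(cells[1], cells[2], cells[3], cells[4])
    o2 <- odds_ratio_ci(cells[4], cells[3], cells[2], cells[1])
    expect_equal(o1$or, o2$or)
    expect_equal(o1$p_raw, o2$p_raw)
    expect_equal(o1$ci_low, o2$ci_low)
  }
})

test_that("bh_adjust reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  set.seed(2)
  for (m in c(2, 3, 5, 8)) {
    p <- runif(m)
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise overall test computes the double-exposure 2x2 per pair", {
  ch <- stratified_pair_cohort(list(ab = c(20, 5), a_only = c(80, 95),
                                    b_only = c(0, 0), none = c(0, 0)))
  res <- pairwise_overall_test(ch)
  expect_identical(nrow(res), 1L)
  expect_equal(res$or, (20 * 95) / (5 * 80))  # 4.75

  # K comorbidities give K(K-1)/2 rows
  set.seed(9)
  X <- matrix(rbinom(200 * 6, 1, 0.3), 200, 6,
              dimnames = list(NULL, sprintf("C%d", 1:6)))
  ch6 <- cohort_matrix(X, rep(c(1, 0), 100))
  expect_identical(nrow(pairwise_overall_test(ch6)), 15L)

  expect_error(pairwise_overall_test(subset_cohort(ch6, comorbidities = 1)),
               "at least 2")
  expect_error(pairwise_overall_test(cohort_matrix(X, rep(1, 200))),
               "cases and controls")
})

test_that("column relabeling permutes but does not change pair results", {
  set.seed(10)
  X <- matrix(rbinom(300 * 5, 1, 0.25), 300, 5,
              dimnames = list(NULL, sprintf("C%d", 1:5)))
  ch <- cohort_matrix(X, rep(c(1, 0), 150))
  perm <- c(4, 2, 5, 1, 3)
  chp <- subset_cohort(ch, comorbidities = perm)
  key <- function(res) {
    k <- paste(pmin(res$comorbidity_a, res$comorbidity_b),
               pmax(res$comorbidity_a, res$comorbidity_b))
    res <- res[order(k), ]
    res[, c("or", "p_raw", "p_fdr")]
  }
  expect_equal(key(pairwise_overall_test(ch)), key(pairwise_overall_test(chp)),
               ignore_attr = TRUE)
})

test_that("untestable pairs are excluded from the FDR family", {
  # C3 never co-occurs with anyone -> its pairs are untestable
  X <- rbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L),
             c(0L, 0L, 1L), c(0L, 0L, 1L))
  colnames(X) <- c("A", "B", "C")
  ch <- cohort_matrix(X, c(1, 0, 1, 0, 1, 0))
  res <- pairwise_overall_test(ch)
  expect_identical(res$testable, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(res$p_fdr[!res$testable])))
  expect_false(any(res$significant_overall[!res$testable]))
})

test_that("directionality sub-tests use disjoint strata and set the pattern", {
  ch <- stratified_pair_cohort(list(ab = c(60, 10), a_only = c(40, 40),
                                    b_only = c(30, 30), none = c(100, 150)))
  ov <- pairwise_overall_test(ch)
  expect_true(ov$significant_overall[1])
  dd <- pairwise_directionality_test(ch, ov)
  expect_equal(dd$ab_vs_a_or[1], (60 * 40) / (10 * 40))
  expect_equal(dd$ab_vs_b_or[1], (60 * 30) / (10 * 30))
  # oracle: the sub-test equals an explicit 2x2 on the strata
  expect_equal(dd$ab_vs_a_p_raw[1], odds_ratio_ci(60, 10, 40, 40)$p_raw)
  expect_identical(dd$direction_pattern[1], "both")

  # identical composition in A&B and A-only strata: test (1) OR = 1
  ch2 <- stratified_pair_cohort(list(ab = c(60, 20), a_only = c(30, 10),
                                     b_only = c(5, 5), none = c(100, 165)))
  ov2 <- pairwise_overall_test(ch2)
  dd2 <- pairwise_directionality_test(ch2, ov2)
  expect_equal(dd2$ab_vs_a_or[1], 1)
  if (dd2$significant_overall[1]) {
    expect_false(dd2$ab_vs_a_p_fdr[1] < 0.05)
  }
})

test_that("replication keeps pairs significant twice with identical direction", {
  mk <- function(a, b, sig, pat) {
    data.frame(comorbidity_a = a, comorbidity_b = b,
               significant_overall = sig, direction_pattern = pat,
               or = 2, stringsAsFactors = FALSE)
  }
  train <- rbind(mk("A", "B", TRUE, "a_only"),
                 mk("A", "C", TRUE, "a_only"),
                 mk("B", "C", TRUE, "both"),
                 mk("A", "D", TRUE, "neither"))
  repl <- rbind(mk("A", "B", TRUE, "a_only"),   # kept
                mk("A", "C", TRUE, "b_only"),   # pattern mismatch
                mk("B", "C", FALSE, "both"),    # not significant
                mk("A", "D", TRUE, "neither"))  # neither direction
  rs <- replicate_pairs(train, repl)
  expect_identical(nrow(rs$pairs), 1L)
  expect_identical(rs$pairs$comorbidity_a, "A")
  expect_identical(rs$unique_comorbidities, c("A", "B"))

  # orientation canonicalization: (B, A) with b_only == (A, B) with a_only
  repl2 <- mk("B", "A", TRUE, "b_only")
  rs2 <- replicate_pairs(mk("A", "B", TRUE, "a_only"), repl2)
  expect_identical(nrow(rs2$pairs), 1L)
  expect_identical(rs2$pairs$direction_pattern, "a_only")
})

test_that("single-comorbidity ORs match the marginal 2x2", {
  X <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L),
             c(0L, 0L), c(0L, 1L), c(1L, 0L), c(0L, 0L))
  colnames(X) <- c("A", "B")
  ch <- cohort_matrix(X, c(1, 1, 1, 1, 0, 0, 0, 0))
  so <- single_comorbidity_or(ch)
  # A: cases 3/4 carriers, controls 1/4
  expect_equal(so$or[so$comorbidity == "A"], (3 * 3) / (1 * 1))
})
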