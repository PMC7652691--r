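align_labels <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      stop("partitions must cover the same element set", call. = FALSE)
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop("partitions must cover the same element set", call. = FALSE)
  }
  if (length(labels_a) < 2L) stop("need at least 2 elements", call. = FALSE)
  if (anyNA(labels_a) || anyNA(labels_b)) {
    stop("partition labels must not contain NA", call. = FALSE)
  }
  list(a = as.integer(factor(labels_a)), b = as.integer(factor(labels_b)))
}

#' Rand index of two partitions
#'
#' Fraction of element pairs on which the two partitions agree: a pair
#' agrees when it is co-clustered in both partitions or separated in both.
#' Computed from the contingency table of the two labelings. When both label
#' vectors are named the elements are matched by name; otherwise positional.
#'
#' @param labels_a,labels_b cluster labels over the same element set
#'   (>= 2 elements).
#' @param adjusted if TRUE return the chance-corrected (adjusted) Rand index
#'   instead of the plain RI (convenience output; the headline statistic is
#'   the plain RI).
#' @return A number in `[0, 1]` (the adjusted variant can be negative).
#' @export
rand_index <- function(labels_a, labels_b, adjusted = FALSE) {
  al <- align_labels(labels_a, labels_b)
  n <- length(al$a)
  tab <- table(al$a, al$b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  if (!adjusted) {
    (total + 2 * sum_ij - sum_a - sum_b) / total
  } else {
    expected <- sum_a * sum_b / total
    denom <- (sum_a + sum_b) / 2 - expected
    if (denom == 0) return(1)
    (sum_ij - expected) / denom
  }
}

#' Permutation significance of the Rand index
#'
#' Null model: the second labeling is shuffled across elements, preserving
#' its cluster sizes; the observed RI is compared against the permuted RIs
#' with the `(r + 1) / (R + 1)` convention. An alternative null drawing both
#' labelings' assignments independently at random (preserving both size
#' profiles) is available via `null`.
#'
#' @param labels_a,labels_b as in [rand_index()].
#' @param n_permutations number of permutations (default 1000).
#' @param seed integer seed.
#' @param null `"shuffle"` (default: permute `labels_b`) or
#'   `"independent"` (permute both labelings).
#' @return Class `ri_result`: list with `ri`, `random_mean`, `random_sd`,
#'   `n_permutations`, `p_value`.
#' @export
ri_significance <- function(labels_a, labels_b, n_permutations = 1000L,
                            seed = 1L, null = c("shuffle", "independent")) {
  null <- match.arg(null)
  al <- align_labels(labels_a, labels_b)
  ri_obs <- rand_index(al$a, al$b)
  n <- length(al$a)
  ris <- withr::with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    a <- if (null == "independent") al$a[sample.int(n)] else al$a
    rand_index(a, al$b[sample.int(n)])
  }, 0))
  structure(list(ri = ri_obs,
                 random_mean = mean(ris),
                 random_sd = stats::sd(ris),
                 n_permutations = n_permutations,
                 p_value = (1 + sum(ris >= ri_obs - 1e-12)) / (n_permutations + 1)),
            class = "ri_result")
}

#' @export
print.ri_result <- function(x, ...) {
  cat(sprintf("<ri_result> RI = %.3f; random mean %.3f (sd %.3f); P = %.4g (%d permutations)\n",
              x$ri, x$random_mean, x$random_sd, x$p_value, x$n_permutations))
  invisible(x)
}
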