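new_test_result <- function(statistic, p_value, method, n_permutations = 0L,
                            seed = NA_integer_, ...) {
  structure(c(list(statistic = statistic, p_value = p_value,
                   method = method, n_permutations = n_permutations,
                   seed = seed), list(...)),
            class = "strp_test")
}

#' @export
print.strp_test <- function(x, ...) {
  cat(x$method, "test", if (!is.null(x$locus)) paste0("(", x$locus, ")"),
      "\n  statistic =", format(x$statistic),
      " p =", format(x$p_value), "\n")
  if (x$n_permutations > 0)
    cat("  ", x$n_permutations, "permutations, seed", x$seed, "\n")
  invisible(x)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Guo-Thompson-style permutation test: the 2N observed gene copies are
#' repeatedly shuffled into N random pairs, and the p-value is the
#' fraction of shuffles whose conditional genotype-array probability
#' (given the allele counts) does not exceed the observed one. The
#' observed arrangement is counted among the permutations
#' (p = (b + 1) / (n_perm + 1)), so p > 0 always. At the default 10,000
#' shuffles the Monte-Carlo standard error of p is at most 0.005.
#'
#' @param g a `genotype_table`.
#' @param locus locus name.
#' @param n_perm number of random pairings.
#' @param seed integer seed (mandatory; the test is deterministic given
#'   it).
#' @return a `strp_test` with fields statistic (conditional
#'   log-probability ordering statistic), p_value, locus and the observed
#'   heterozygote count `het_obs`.
#' @export
hwe_exact_mc <- function(g, locus, n_perm = 10000L, seed) {
  if (missing(seed)) stop("hwe_exact_mc requires an explicit seed")
  calls <- locus_calls(g, locus)
  if (calls$n < 2L) stop("need at least 2 typed individuals at ", locus)
  alleles <- sort_alleles(unique(c(calls$a1, calls$a2)))
  het <- sum(calls$a1 != calls$a2)
  if (length(alleles) < 2L) {
    warning("locus ", locus, " is monomorphic; HWE p = 1")
    return(new_test_result(0, 1, "mc_exact", 0L, as.integer(seed),
                           locus = locus, het_obs = het))
  }
  c1 <- match(calls$a1, alleles) - 1L
  c2 <- match(calls$a2, alleles) - 1L
  set.seed(seed)
  res <- hwe_mc_cpp(c1, c2, length(alleles), as.integer(n_perm))
  new_test_result(res$stat, (res$n_le + 1) / (n_perm + 1), "mc_exact",
                  as.integer(n_perm), as.integer(seed),
                  locus = locus, het_obs = het)
}

#' Chi-square test of Hardy-Weinberg proportions
#'
#' Pearson chi-square of observed genotype-class counts against the
#' proportions expected from the counting-estimated allele frequencies.
#' Classes with expected count below 1 are pooled into one class; degrees
#' of freedom = (classes after pooling) - (number of alleles), floored at
#' 1. Intended as a large-sample cross-check of [hwe_exact_mc()].
#'
#' @inheritParams hwe_exact_mc
#' @return a `strp_test` with method `"chi2"` and a `df` field.
#' @export
hwe_chi2 <- function(g, locus) {
  calls <- locus_calls(g, locus)
  if (calls$n < 2L) stop("need at least 2 typed individuals at ", locus)
  fr <- estimate_allele_frequencies(g, locus)
  alleles <- names(fr)
  k <- length(alleles)
  het <- sum(calls$a1 != calls$a2)
  if (k < 2L) {
    warning("locus ", locus, " is monomorphic; HWE p = 1")
    return(new_test_result(0, 1, "chi2", locus = locus, het_obs = het,
                           df = 0L))
  }
  n <- calls$n
  i1 <- match(calls$a1, alleles)
  i2 <- match(calls$a2, alleles)
  obs <- exp_ <- numeric(0)
  for (i in seq_len(k)) for (j in i:k) {
    o <- sum((i1 == i & i2 == j) | (i1 == j & i2 == i))
    e <- if (i == j) n * fr[i]^2 else 2 * n * fr[i] * fr[j]
    obs <- c(obs, o)
    exp_ <- c(exp_, e)
  }
  pool <- exp_ < 1
  if (any(pool)) {
    obs <- c(obs[!pool], sum(obs[pool]))
    exp_ <- c(exp_[!pool], sum(exp_[pool]))
  }
  stat <- sum((obs - exp_)^2 / exp_)
  df <- max(1L, length(obs) - k)
  new_test_result(stat, pchisq(stat, df, lower.tail = FALSE), "chi2",
                  locus = locus, het_obs = het, df = df)
}

#' Bonferroni multiple-testing decisions
#'
#' @param p_values numeric vector of raw p-values.
#' @param alpha family-wise error rate.
#' @return list with `m` (test count), `threshold` (= alpha / m),
#'   `significant` (logical, p <= threshold) and `raw_significant`
#'   (p <= alpha).
#' @export
bonferroni_adjust <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m < 1L) stop("no p-values supplied")
  thr <- alpha / m
  list(m = m, threshold = thr,
       significant = p_values <= thr,
       raw_significant = p_values <= alpha)
}
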