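#' Shared locus panel of a set of populations
#'
#' @param pops list of `freq_table` objects.
#' @return character vector of loci present in every population.
#' @export
shared_loci <- function(pops) {
  Reduce(intersect, lapply(pops, function(p) names(p$loci)))
}

align_freqs <- function(fx, fy) {
  alleles <- sort_alleles(unique(c(names(fx), names(fy))))
  x <- fx[alleles]; x[is.na(x)] <- 0
  y <- fy[alleles]; y[is.na(y)] <- 0
  names(x) <- names(y) <- alleles
  list(x = unname(x), y = unname(y))
}

#' Nei's DA genetic distance between two populations
#'
#' DA = 1 - (1/r) * sum_j sum_i sqrt(x_ij * y_ij) over r shared loci.
#' Allele spaces are unioned per locus with absent alleles at frequency
#' 0, so the value is invariant to padding and to locus or allele order.
#' DA is a symmetric premetric on \[0, 1\]: 0 iff the frequency vectors
#' agree on the panel, 1 when the populations share no alleles. The
#' triangle inequality is not guaranteed.
#'
#' @param x,y `freq_table` objects.
#' @param loci shared locus panel; defaults to the intersection.
#' @return DA in \[0, 1\].
#' @export
nei_da_pair <- function(x, y, loci = NULL) {
  if (is.null(loci)) loci <- intersect(names(x$loci), names(y$loci))
  if (length(loci) == 0L) stop("no shared loci between ",
                               x$population, " and ", y$population)
  bc <- vapply(loci, function(L) {
    al <- align_freqs(x$loci[[L]], y$loci[[L]])
    sum(sqrt(al$x * al$y))
  }, 1.0)
  max(0, 1 - mean(bc))
}

#' Nei's DA distance matrix over a population set
#'
#' @param pops list of `freq_table` objects (>= 2, distinct names).
#' @param loci shared panel; defaults to the intersection over all
#'   populations.
#' @return labelled symmetric zero-diagonal matrix.
#' @export
nei_da_matrix <- function(pops, loci = NULL) {
  if (length(pops) < 2L) stop("need at least 2 populations")
  labels <- vapply(pops, function(p) p$population, "")
  if (anyDuplicated(labels)) stop("duplicate population labels")
  if (is.null(loci)) loci <- shared_loci(pops)
  if (length(loci) == 0L) stop("no loci shared by all populations")
  n <- length(pops)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- nei_da_pair(pops[[i]], pops[[j]], loci)
  }
  m
}

#' Allele-permutation test of population differentiation at one locus
#'
#' Homogeneity test of a 2 x k allele-count table: the statistic is the
#' G2 log-likelihood ratio, and the null is generated by randomly
#' reassigning the pooled gene copies to the two populations preserving
#' both totals. For published frequency tables, integer counts are first
#' recovered with [reconstruct_counts()]. Shares its null hypothesis (no
#' allele-frequency differentiation at the locus) with the
#' locus-by-locus AMOVA tests of standard population-genetics software,
#' while needing only allele counts rather than genotypes.
#'
#' @param x_counts,y_counts named integer vectors of allele counts.
#' @param n_perm number of permutations.
#' @param seed integer seed (mandatory).
#' @return a `strp_test` (add-one p-value).
#' @export
differentiation_test <- function(x_counts, y_counts, n_perm = 10000L, seed) {
  if (missing(seed)) stop("differentiation_test requires an explicit seed")
  alleles <- sort_alleles(unique(c(names(x_counts), names(y_counts))))
  cx <- x_counts[alleles]; cx[is.na(cx)] <- 0L
  cy <- y_counts[alleles]; cy[is.na(cy)] <- 0L
  if (sum(cx) < 2L || sum(cy) < 2L)
    stop("each population needs at least 2 gene copies")
  set.seed(seed)
  res <- difftest_perm_cpp(as.integer(cx), as.integer(cy),
                           as.integer(n_perm))
  new_test_result(res$g2, (res$n_ge + 1) / (n_perm + 1),
                  "allele_permutation_g2", as.integer(n_perm),
                  as.integer(seed))
}

#' Locus-by-locus differentiation p-values across population pairs
#'
#' Runs [differentiation_test()] for every (population pair, locus)
#' combination on the shared panel. The Bonferroni family size m is
#' reported explicitly, never silently applied: in `"focal"` mode
#' m = (number of pairs involving the first population) x loci; in
#' `"allpairs"` mode m = all pairs x loci.
#'
#' @param pops list of `freq_table` objects.
#' @param alpha family-wise error rate.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param m_mode `"focal"` (pairs involving `pops[[1]]`) or
#'   `"allpairs"`.
#' @param loci shared panel; defaults to the intersection.
#' @return list with `p_values` (data.frame pop_a, pop_b, locus, g2,
#'   p_value, significant), `m`, `threshold`, and `significant_per_pair`
#'   (count of Bonferroni-significant loci per pair).
#' @export
pairwise_differentiation_table <- function(pops, alpha = 0.05,
                                           n_perm = 10000L, seed,
                                           m_mode = c("focal", "allpairs"),
                                           loci = NULL) {
  if (missing(seed)) stop("pairwise_differentiation_table requires a seed")
  m_mode <- match.arg(m_mode)
  if (is.null(loci)) loci <- shared_loci(pops)
  counts <- lapply(pops, reconstruct_counts)
  labels <- vapply(pops, function(p) p$population, "")
  pairs <- utils::combn(seq_along(pops), 2L)
  if (m_mode == "focal")
    pairs <- pairs[, pairs[1, ] == 1L, drop = FALSE]
  rows <- list()
  k <- 0L
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    for (L in loci) {
      k <- k + 1L
      t <- differentiation_test(counts[[i]][[L]], counts[[j]][[L]],
                                n_perm, seed = seed + k)
      rows[[k]] <- data.frame(pop_a = labels[i], pop_b = labels[j],
                              locus = L, g2 = t$statistic,
                              p_value = t$p_value)
    }
  }
  df <- do.call(rbind, rows)
  bf <- bonferroni_adjust(df$p_value, alpha)
  df$significant <- bf$significant
  per_pair <- tapply(df$significant, paste(df$pop_a, df$pop_b, sep = " vs "),
                     sum)
  list(p_values = df, m = bf$m, threshold = bf$threshold,
       significant_per_pair = per_pair)
}
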