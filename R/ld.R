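#' Genotypic linkage-disequilibrium permutation test
#'
#' G2 (log-likelihood-ratio) statistic of the two-locus genotype-class
#' contingency table; the null distribution is generated by permuting the
#' second locus's genotypes across individuals, which breaks any
#' between-locus association while preserving both single-locus genotype
#' arrays. Raw STR data are unphased, so the test operates on genotype
#' (not haplotype) classes. The EM-based composite r-squared
#' ([composite_r2()]) is attached to the result.
#'
#' @param g a `genotype_table`.
#' @param locus_a,locus_b locus names.
#' @param n_perm number of permutations.
#' @param seed integer seed (mandatory).
#' @return a `strp_test` with fields `pair` and `r_squared`.
#' @export
ld_permutation_test <- function(g, locus_a, locus_b, n_perm = 10000L, seed) {
  if (missing(seed)) stop("ld_permutation_test requires an explicit seed")
  ca <- locus_calls_pair(g, locus_a, locus_b)
  if (ca$n < 2L) stop("need at least 2 individuals typed at both loci")
  gen_a <- paste(ca$a1, ca$a2, sep = "/")
  gen_b <- paste(ca$b1, ca$b2, sep = "/")
  pair <- c(locus_a, locus_b)
  if (length(unique(c(ca$a1, ca$a2))) < 2L ||
      length(unique(c(ca$b1, ca$b2))) < 2L) {
    warning("monomorphic locus in pair; LD p = 1, r2 = 0")
    return(new_test_result(0, 1, "g2_permutation", 0L, as.integer(seed),
                           pair = pair, r_squared = 0))
  }
  la <- sort(unique(gen_a)); lb <- sort(unique(gen_b))
  set.seed(seed)
  res <- g2_perm_cpp(match(gen_a, la) - 1L, match(gen_b, lb) - 1L,
                     length(la), length(lb), as.integer(n_perm))
  r2 <- composite_r2(g, locus_a, locus_b)
  new_test_result(res$g2, (res$n_ge + 1) / (n_perm + 1), "g2_permutation",
                  as.integer(n_perm), as.integer(seed),
                  pair = pair, r_squared = r2)
}

locus_calls_pair <- function(g, locus_a, locus_b) {
  if (!locus_a %in% g$loci) stop("unknown locus: ", locus_a)
  if (!locus_b %in% g$loci) stop("unknown locus: ", locus_b)
  ok <- !is.na(g$a1[, locus_a]) & !is.na(g$a1[, locus_b])
  list(a1 = g$a1[ok, locus_a], a2 = g$a2[ok, locus_a],
       b1 = g$a1[ok, locus_b], b2 = g$a2[ok, locus_b], n = sum(ok))
}

#' Composite r-squared from EM haplotype frequencies
#'
#' Two-locus haplotype frequencies are estimated from unphased genotypes
#' by expectation-maximization (double heterozygotes split between their
#' two phasings in proportion to current haplotype frequencies; all other
#' genotypes phase uniquely). Per allele pair,
#' D_ij = h_ij - p_i q_j and r2_ij = D_ij^2 / (p_i (1-p_i) q_j (1-q_j));
#' the reported statistic is the frequency-weighted mean
#' sum_ij p_i q_j r2_ij, which is bounded in \[0, 1\] and reduces to the
#' usual r2 for biallelic loci.
#'
#' @inheritParams ld_permutation_test
#' @param max_em_iter iteration cap.
#' @param tol convergence tolerance on the largest absolute change in any
#'   haplotype frequency.
#' @return r-squared in \[0, 1\]; attribute `"converged"` reports EM
#'   convergence, attribute `"haplotypes"` the frequency matrix.
#' @export
composite_r2 <- function(g, locus_a, locus_b, max_em_iter = 10000L,
                         tol = 1e-6) {
  ca <- locus_calls_pair(g, locus_a, locus_b)
  if (ca$n < 2L) stop("need at least 2 individuals typed at both loci")
  aa <- sort_alleles(unique(c(ca$a1, ca$a2)))
  bb <- sort_alleles(unique(c(ca$b1, ca$b2)))
  ka <- length(aa); kb <- length(bb)
  if (ka < 2L || kb < 2L) {
    out <- 0
    attr(out, "converged") <- TRUE
    return(out)
  }
  i1 <- match(ca$a1, aa); i2 <- match(ca$a2, aa)
  j1 <- match(ca$b1, bb); j2 <- match(ca$b2, bb)
  p <- tabulate(c(i1, i2), ka) / (2 * ca$n)
  q <- tabulate(c(j1, j2), kb) / (2 * ca$n)
  h <- outer(p, q)                       # linkage-equilibrium start
  dbl <- i1 != i2 & j1 != j2             # ambiguous phase
  # unambiguous individuals contribute both haplotypes directly, once
  base <- numeric(ka * kb)
  fixed <- c((j1[!dbl] - 1L) * ka + i1[!dbl],
             (j2[!dbl] - 1L) * ka + i2[!dbl])
  tb <- tabulate(fixed, ka * kb)
  base <- base + tb
  # collapse ambiguous individuals to distinct genotype patterns
  pat <- paste(i1[dbl], i2[dbl], j1[dbl], j2[dbl])
  up <- !duplicated(pat)
  mult <- as.numeric(table(pat)[pat[up]])
  pi1 <- i1[dbl][up]; pi2 <- i2[dbl][up]
  pj1 <- j1[dbl][up]; pj2 <- j2[dbl][up]
  cis1 <- (pj1 - 1L) * ka + pi1; cis2 <- (pj2 - 1L) * ka + pi2
  tr1 <- (pj2 - 1L) * ka + pi1; tr2 <- (pj1 - 1L) * ka + pi2
  converged <- length(mult) == 0L
  for (it in seq_len(if (converged) 0L else max_em_iter)) {
    w1 <- h[cis1] * h[cis2]
    w2 <- h[tr1] * h[tr2]
    tot <- w1 + w2
    w <- ifelse(tot > 0, w1 / tot, 0.5)
    idx <- c(cis1, cis2, tr1, tr2)
    wts <- c(w, w, 1 - w, 1 - w) * rep(mult, 4L)
    cnt <- base
    add <- rowsum(wts, idx)
    cnt[as.integer(rownames(add))] <- cnt[as.integer(rownames(add))] + add
    hn <- matrix(cnt / (2 * ca$n), ka, kb)
    delta <- max(abs(hn - h))
    h <- hn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (length(mult) == 0L) h <- matrix(base / (2 * ca$n), ka, kb)
  if (!converged)
    warning("haplotype EM did not converge in ", max_em_iter, " iterations")
  D <- h - outer(p, q)
  denom <- outer(p * (1 - p), q * (1 - q))
  r2m <- ifelse(denom > 0, D^2 / denom, 0)
  out <- sum(outer(p, q) * r2m)
  attr(out, "converged") <- converged
  attr(out, "haplotypes") <- h
  out
}

#' All pairwise LD tests for a genotype table
#'
#' Runs [ld_permutation_test()] for every unordered locus pair (C(L, 2)
#' pairs) and reports the Bonferroni threshold alongside the raw
#' p-values.
#'
#' @inheritParams ld_permutation_test
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return data.frame with one row per pair: locus_a, locus_b, g2,
#'   p_value, r_squared, significant_raw, significant_bonferroni;
#'   attributes `"m"` and `"threshold"`.
#' @export
ld_pairwise <- function(g, n_perm = 10000L, seed, alpha = 0.05) {
  if (missing(seed)) stop("ld_pairwise requires an explicit seed")
  pairs <- utils::combn(g$loci, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    t <- ld_permutation_test(g, pairs[1, i], pairs[2, i], n_perm,
                             seed = seed + i - 1L)
    data.frame(locus_a = pairs[1, i], locus_b = pairs[2, i],
               g2 = t$statistic, p_value = t$p_value,
               r_squared = as.numeric(t$r_squared))
  })
  out <- do.call(rbind, res)
  bf <- bonferroni_adjust(out$p_value, alpha)
  out$significant_raw <- bf$raw_significant
  out$significant_bonferroni <- bf$significant
  attr(out, "m") <- bf$m
  attr(out, "threshold") <- bf$threshold
  out
}
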