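make_two_locus <- function(n, pa, pb, seed) {
  set.seed(seed)
  a1 <- sample(names(pa), n, TRUE, pa)
  a2 <- sample(names(pa), n, TRUE, pa)
  b1 <- sample(names(pb), n, TRUE, pb)
  b2 <- sample(names(pb), n, TRUE, pb)
  genotype_table(sprintf("s%04d", 1:n), c("A", "B"),
                 cbind(a1, b1), cbind(a2, b2))
}

test_that("a duplicated locus is detected with r2 = 1 in the biallelic case", {
  set.seed(4)
  n <- 200
  a1 <- sample(c("9", "11"), n, TRUE)
  a2 <- sample(c("9", "11"), n, TRUE)
  g <- genotype_table(sprintf("s%03d", 1:n), c("A", "B"),
                      cbind(a1, a1), cbind(a2, a2))
  t1 <- ld_permutation_test(g, "A", "B", n_perm = 999, seed = 8)
  expect_lte(t1$p_value, 0.001)
  expect_equal(as.numeric(t1$r_squared), 1, tolerance = 1e-6)
})

test_that("a duplicated multi-allelic locus is detected", {
  set.seed(5)
  n <- 200
  p <- c(`9` = .4, `11` = .3, `13` = .2, `15` = .1)
  a1 <- sample(names(p), n, TRUE, p)
  a2 <- sample(names(p), n, TRUE, p)
  g <- genotype_table(sprintf("s%03d", 1:n), c("A", "B"),
                      cbind(a1, a1), cbind(a2, a2))
  t1 <- ld_permutation_test(g, "A", "B", n_perm = 999, seed = 9)
  expect_lte(t1$p_value, 0.001)
  # the frequency-weighted multi-allelic aggregate is well below 1 even at
  # perfect dependence (off-diagonal allele pairs contribute r2_ij < 1)
  expect_gt(as.numeric(t1$r_squared), 0.3)
})

test_that("a monomorphic partner gives p = 1 and r2 = 0", {
  n <- 50
  set.seed(6)
  a1 <- sample(c("9", "11"), n, TRUE)
  a2 <- sample(c("9", "11"), n, TRUE)
  g <- genotype_table(sprintf("s%02d", 1:n), c("A", "B"),
                      cbind(a1, rep("7", n)), cbind(a2, rep("7", n)))
  expect_warning(t1 <- ld_permutation_test(g, "A", "B", 99, seed = 2),
                 "monomorphic")
  expect_equal(t1$p_value, 1)
  expect_equal(as.numeric(t1$r_squared), 0)
})

test_that("EM equals direct counting when phase is unambiguous", {
  # haplotype pairs chosen so no individual is doubly heterozygous
  haps <- list(c("AB", "AB"), c("AB", "Ab"), c("AB", "aB"),
               c("Ab", "ab") , c("aB", "ab"), c("ab", "ab"),
               c("AB", "AB"), c("Ab", "Ab"))
  sp <- function(h) c(substr(h, 1, 1), substr(h, 2, 2))
  a1 <- vapply(haps, function(h) sp(h[1])[1], "")
  a2 <- vapply(haps, function(h) sp(h[2])[1], "")
  b1 <- vapply(haps, function(h) sp(h[1])[2], "")
  b2 <- vapply(haps, function(h) sp(h[2])[2], "")
  # recode letters to numeric STR-style labels
  m <- c(A = "9", a = "11", B = "7", b = "8")
  g <- genotype_table(sprintf("s%02d", seq_along(haps)), c("LA", "LB"),
                      cbind(m[a1], m[b1]), cbind(m[a2], m[b2]))
  hh <- unlist(haps)
  r2_truth <- r2_closed_form(sum(hh == "AB"), sum(hh == "Ab"),
                             sum(hh == "aB"), sum(hh == "ab"))
  r2_em <- composite_r2(g, "LA", "LB")
  expect_equal(as.numeric(r2_em), r2_truth, tolerance = 1e-6)
  expect_true(attr(r2_em, "converged"))
})

test_that("composite r2 is symmetric in locus order", {
  ft <- load_guanzhong_freqs()
  g <- simulate_genotypes(ft, 150, 0, seed = 14)
  r_ab <- as.numeric(composite_r2(g, "D2S1338", "D16S539"))
  r_ba <- as.numeric(composite_r2(g, "D16S539", "D2S1338"))
  expect_equal(r_ab, r_ba, tolerance = 1e-10)
})

test_that("biallelic composite r2 matches squared allele-count correlation", {
  # draw phased haplotypes with built-in LD, pair them at random (HWE)
  set.seed(33)
  n <- 2000
  hfreq <- c(AB = 0.35, Ab = 0.15, aB = 0.1, ab = 0.4)
  draw <- function(k) sample(names(hfreq), k, TRUE, hfreq)
  h1 <- draw(n); h2 <- draw(n)
  lab <- c(A = "9", a = "11", B = "7", b = "8")
  g <- genotype_table(sprintf("s%04d", 1:n), c("LA", "LB"),
                      cbind(lab[substr(h1, 1, 1)], lab[substr(h1, 2, 2)]),
                      cbind(lab[substr(h2, 1, 1)], lab[substr(h2, 2, 2)]))
  # oracle: squared Pearson correlation of per-individual allele counts
  cnt_a <- (substr(h1, 1, 1) == "A") + (substr(h2, 1, 1) == "A")
  cnt_b <- (substr(h1, 2, 2) == "B") + (substr(h2, 2, 2) == "B")
  r2_cor <- cor(cnt_a, cnt_b)^2
  r2_em <- as.numeric(composite_r2(g, "LA", "LB"))
  expect_lt(abs(r2_em - r2_cor), 0.02)
})

test_that("independent loci give small r2 and well-behaved p-values", {
  p <- c(`9` = .3, `11` = .3, `13` = .25, `15` = .15)
  g <- make_two_locus(5000, p, p, seed = 55)
  expect_lt(as.numeric(composite_r2(g, "A", "B")), 0.01)
  t1 <- ld_permutation_test(g, "A", "B", 199, seed = 3)
  expect_gt(t1$p_value, 0.001)
})

test_that("pairwise LD enumerates C(L,2) pairs with Bonferroni metadata", {
  ft <- load_guanzhong_freqs()
  sub <- freq_table(ft$population, ft$loci[1:6], ft$gene_copies)
  g <- simulate_genotypes(sub, 60, 0, seed = 19)
  tab <- ld_pairwise(g, n_perm = 99, seed = 41)
  expect_equal(nrow(tab), choose(6, 2))
  expect_equal(attr(tab, "m"), choose(6, 2))
  expect_equal(attr(tab, "threshold"), 0.05 / choose(6, 2))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(all(tab$r_squared >= 0 & tab$r_squared <= 1))
})
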