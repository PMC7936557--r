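test_that("allele frequencies are counting estimates", {
  g <- gt(L = list(c("15", "15"), c("15", "15")))
  expect_equal(estimate_allele_frequencies(g, "L"), c(`15` = 1),
               ignore_attr = TRUE)
  g2 <- gt(L = list(c("9", "11")))
  expect_equal(estimate_allele_frequencies(g2, "L"),
               c(`9` = 0.5, `11` = 0.5), ignore_attr = TRUE)
  g3 <- gt(L = list(c("9", "11"), c("9", "9"), c("11", "12"),
                    c("9", "12"), c("11", "11")))
  expect_equal(estimate_allele_frequencies(g3, "L"),
               c(`9` = 0.4, `11` = 0.4, `12` = 0.2), ignore_attr = TRUE)
  expect_equal(attr(estimate_allele_frequencies(g3, "L"), "gene_copies"), 10L)
})

test_that("observed heterozygosity is the heterozygote fraction", {
  hom <- gt(L = list(c("9", "9"), c("11", "11")))
  expect_equal(observed_heterozygosity(hom, "L"), 0)
  het <- gt(L = list(c("9", "10"), c("11", "12")))
  expect_equal(observed_heterozygosity(het, "L"), 1)
  mix <- gt(L = list(c("9", "10"), c("9", "9"), c("9", "11"),
                     c("10", "10"), c("10", "11")))
  expect_equal(observed_heterozygosity(mix, "L"), 0.6)
})

test_that("unbiased expected heterozygosity matches closed forms", {
  expect_equal(expected_heterozygosity(c(a = 1), 1180), 0)
  expect_equal(expected_heterozygosity(c(a = 0.5, b = 0.5), 1180),
               1180 / 1179 * 0.5)
  expect_equal(round(expected_heterozygosity(c(a = 0.5, b = 0.5), 1180), 6),
               0.500424)
  expect_error(expected_heterozygosity(c(a = 1), 1), "at least 2")
})

test_that("PIC matches direct evaluation", {
  expect_equal(pic(c(a = 1)), 0)
  expect_equal(pic(c(a = 0.5, b = 0.5)), 0.375)
})

test_that("matching probability from observed genotype classes", {
  same <- gt(L = list(c("9", "9"), c("9", "9"), c("9", "9")))
  expect_equal(match_probability(same, "L"), list(mp = 1, pd = 0))
  dist4 <- gt(L = list(c("9", "9"), c("9", "10"), c("10", "10"),
                       c("9", "11")))
  expect_equal(match_probability(dist4, "L")$mp, 1 / 4)
  aabb <- gt(L = list(c("9", "9"), c("9", "9"), c("9", "10"), c("9", "10")))
  expect_equal(match_probability(aabb, "L")$mp, 0.5)
})

test_that("exclusion power hits endpoints and increases strictly in h", {
  expect_equal(power_of_exclusion(0), 0)
  expect_equal(power_of_exclusion(1), 1)
  grid <- seq(0, 1, by = 0.01)
  pe <- power_of_exclusion(grid)
  expect_true(all(diff(pe) > 0))
  expect_true(all(pe >= 0 & pe <= 1))
})

test_that("digit-string expansion of 1 - p is exact", {
  # 1 - 2^-20 is exactly representable; sprintf prints its exact digits
  p <- 2^-20
  expect_equal(sub("0+$", "", one_minus_decimal(p, 40L)),
               sub("0+$", "", sprintf("%.40f", 1 - p)))
  expect_equal(one_minus_decimal(0), "1")
  expect_equal(one_minus_decimal(1), "0")
  expect_match(one_minus_decimal(1e-28), "^0\\.9{27}")
})

test_that("combined powers multiply across loci", {
  one <- combined_powers(0.25, 0.5)
  expect_equal(one$mp_product, 0.25)
  expect_match(one$cpd, "^0\\.75")
  two <- combined_powers(c(0.1, 0.1), c(0, 0))
  expect_equal(two$mp_product, 0.01)           # CPD = 0.99
  expect_match(two$cpd, "^0\\.9[89]")          # digits of the double 0.1^2
  exact <- combined_powers(c(0.25, 0.25), c(0, 0))
  expect_match(exact$cpd, "^0\\.9375")
  expect_equal(two$pe_residual, 1)
  expect_equal(two$cpe, "0")  # CPE = 0 when every PE is 0
  expect_error(combined_powers(numeric(0), numeric(0)), "at least one")
})

test_that("combined powers are order-invariant and monotone in loci", {
  set.seed(9)
  mp <- runif(8, 0.02, 0.3)
  pe <- runif(8, 0.3, 0.8)
  a <- combined_powers(mp, pe)
  b <- combined_powers(rev(mp), sample(pe))
  expect_equal(a$mp_product, b$mp_product, tolerance = 1e-14)
  expect_equal(a$cpe, b$cpe)
  # adding a locus never decreases CPD or CPE
  more <- combined_powers(c(mp, 0.5), c(pe, 0.1))
  expect_true(more$mp_product <= a$mp_product)
  expect_true(more$pe_residual <= a$pe_residual)
})

test_that("genotype-mode summary satisfies the per-locus identities", {
  ft <- load_guanzhong_freqs()
  g <- simulate_genotypes(ft, 300, 0, seed = 21)
  fs <- forensic_summary(g = g)
  expect_equal(nrow(fs), 22L)
  num <- fs[c("Ho", "He", "PIC", "MP", "PD", "PE")]
  expect_true(all(num >= 0 & num <= 1))
  expect_equal(fs$PD + fs$MP, rep(1, 22))
  for (i in seq_len(nrow(fs))) {
    fr <- estimate_allele_frequencies(g, fs$locus[i])
    raw <- 1 - sum(fr^2)
    expect_lt(fs$PIC[i], raw)
    expect_gt(fs$He[i], raw)  # unbiased correction exceeds the raw form
  }
  comb <- attr(fs, "combined")
  expect_match(comb$cpd, "^0\\.9")
  expect_match(comb$cpe, "^0\\.9")
})

test_that("frequency-mode summary flags genotype-only parameters", {
  ft <- load_guanzhong_freqs()
  ho <- c(D10S1435 = 0.7407, D7S3048 = 0.8881)
  fs <- forensic_summary(freqs = ft, ho = ho)
  expect_true(all(is.na(fs$MP)))
  expect_true(all(is.na(fs$PD)))
  expect_equal(fs$PE[fs$locus == "D10S1435"],
               power_of_exclusion(0.7407))
  expect_true(is.na(fs$PE[fs$locus == "D1S1656"]))
  expect_error(forensic_summary(), "exactly one")
  mono <- freq_table("p", list(L = c(`10` = 1)), 10L)
  fsm <- forensic_summary(freqs = mono)
  expect_equal(fsm$PIC, 0)
  expect_equal(fsm$He, 0)
})

test_that("large HWE samples agree with expectation formulas", {
  ft <- load_guanzhong_freqs()
  sub <- freq_table(ft$population, ft$loci[c("D4S2366", "D16S539", "D2S1338")],
                    ft$gene_copies)
  g <- simulate_genotypes(sub, 5000, 0, seed = 31)
  fs <- forensic_summary(g = g)
  expect_true(all(abs(fs$Ho - fs$He) < 0.02))
  for (i in seq_len(nrow(fs))) {
    p <- ft$loci[[fs$locus[i]]]
    p <- p / sum(p)
    mp_hwe <- sum((p^2)^2) + sum((2 * outer(p, p))[upper.tri(diag(length(p)))]^2)
    expect_lt(abs(fs$MP[i] - mp_hwe), 0.01)
  }
})
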