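test_that("allele labels sort by repeat value with microvariants interleaved", {
  expect_equal(sort_alleles(c("16", "15", "15.3", "9")),
               c("9", "15", "15.3", "16"))
  expect_error(allele_value(c("15", "x")), "non-numeric")
})

test_that("bundled frequency table loads and validates", {
  ft <- load_guanzhong_freqs()
  expect_s3_class(ft, "freq_table")
  expect_equal(ft$population, "Guanzhong Han")
  expect_equal(ft$gene_copies, 1180L)
  expect_length(ft$loci, 22L)
  expect_silent(validate_freq_table(ft))
})

test_that("degenerate and invalid frequency tables are handled", {
  one <- freq_table("p", list(L = c(`10` = 1.0)), 10L)
  expect_silent(validate_freq_table(one))
  expect_error(
    freq_table("p", list(BAD = c(`10` = 0.5, `11` = 0.4)), 10L),
    "BAD")
  expect_error(
    freq_table("p", list(L = c(`10` = 1.2)), 10L),
    "outside")
  expect_error(freq_table("p", list(L = c(`10` = 1.0)), 11L), "even")
})

test_that("frequency CSV reader rejects duplicates and round-trips", {
  ft <- load_guanzhong_freqs()
  tmp <- tempfile(fileext = ".csv")
  write_freq_table(ft, tmp)
  back <- read_freq_table(tmp)
  expect_equal(back$loci, ft$loci, tolerance = 1e-12)
  expect_equal(back$gene_copies, ft$gene_copies)
  bad <- c("#population=p", "#gene_copies=10", "locus,allele,frequency",
           "L,10,0.5", "L,10,0.5")
  f2 <- tempfile(fileext = ".csv")
  writeLines(bad, f2)
  expect_error(read_freq_table(f2), "duplicate")
})

test_that("genotype CSV round-trips and half calls demote to missing", {
  ft <- load_guanzhong_freqs()
  g <- simulate_genotypes(ft, 25, 0, seed = 11)
  tmp <- tempfile(fileext = ".csv")
  write_genotype_table(g, tmp)
  back <- read_genotype_table(tmp)
  expect_identical(back$a1, g$a1)
  expect_identical(back$a2, g$a2)
  expect_identical(back$samples, g$samples)

  lines <- c("sample,L.1,L.2", "s1,10,11", "s2,10,")
  f2 <- tempfile(fileext = ".csv")
  writeLines(lines, f2)
  expect_warning(g2 <- read_genotype_table(f2), "missing")
  expect_true(is.na(g2$a1["s2", "L"]))
  expect_equal(locus_calls(g2, "L")$n, 1L)
  writeLines("sample,L.1,L.2", f2)
  expect_error(read_genotype_table(f2), "no samples")
})

test_that("genotype pairs are unordered", {
  g1 <- gt(L = list(c("11", "9"), c("9", "11")))
  expect_identical(g1$a1[1, ], g1$a1[2, ])
  expect_identical(g1$a2[1, ], g1$a2[2, ])
})

test_that("reconstructed counts match 2N within rounding slack", {
  ft <- load_guanzhong_freqs()
  cnt <- reconstruct_counts(ft)
  expect_equal(cnt$D4S2366[["9"]], round(0.3331 * 1180))
  expect_true(all(unlist(cnt) >= 1L))
  k <- vapply(ft$loci, length, 1L)
  dev <- abs(attr(cnt, "sum_deviation"))
  expect_true(all(dev <= k / 2))
  # frequency 0.0008 with 2N = 1180 -> a single gene copy
  expect_equal(cnt$D1S1656[["10"]], 1L)
  # re-normalizing reproduces the published frequencies to 5e-4
  for (L in names(cnt)) {
    renorm <- cnt[[L]] / sum(cnt[[L]])
    expect_true(max(abs(renorm - ft$loci[[L]])) < 5e-4)
  }
})

test_that("simple count reconstruction cases", {
  ftab <- freq_table("p", list(L = c(`10` = 0.5, `11` = 0.5)), 10L)
  expect_equal(unname(reconstruct_counts(ftab)$L), c(5L, 5L))
})

test_that("distance matrices round-trip through PHYLIP and CSV", {
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tmp <- tempfile(fileext = ".phy")
  write_distance_matrix(m, tmp, "phylip")
  expect_length(readLines(tmp), 3L)
  expect_equal(read_distance_matrix(tmp, "phylip"), m, tolerance = 1e-6)

  set.seed(42)
  x <- matrix(runif(14 * 3), 14)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(sprintf("Pop%02d", 1:14), sprintf("Pop%02d", 1:14))
  f <- tempfile(fileext = ".phy")
  write_distance_matrix(d, f, "phylip")
  expect_equal(read_distance_matrix(f, "phylip"), d, tolerance = 1e-6)
  fc <- tempfile(fileext = ".csv")
  write_distance_matrix(d, fc, "csv")
  expect_equal(read_distance_matrix(fc, "csv"), d, tolerance = 1e-6)
})

test_that("PHYLIP labels truncate with collision detection", {
  nm <- c("VeryLongNameOne", "VeryLongNameTwo")
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(nm, nm))
  expect_error(write_distance_matrix(m, tempfile(), "phylip"), "collide")
  nm2 <- c("Short", "AlsoShort")
  dimnames(m) <- list(nm2, nm2)
  expect_silent(write_distance_matrix(m, tempfile(fileext = ".phy"), "phylip"))
})

test_that("Newick writer round-trips topology and lengths", {
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
              dimnames = list(lab, lab))
  tr <- neighbor_joining(d)
  tmp <- tempfile(fileext = ".nwk")
  write_newick(tr, tmp)
  txt <- readLines(tmp)
  expect_match(txt, ";$")
  back <- read_newick(tmp)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(cophenetic(back)[lab, lab], cophenetic(tr)[lab, lab],
               tolerance = 1e-6)
})

test_that("labels with spaces are underscore-escaped in Newick", {
  nm <- c("Pop One", "Pop Two", "Pop Three")
  m <- matrix(c(0, 1, 2, 1, 0, 1.5, 2, 1.5, 0), 3, 3, dimnames = list(nm, nm))
  tr <- neighbor_joining(m)
  expect_setequal(tr$tip.label, c("Pop_One", "Pop_Two", "Pop_Three"))
})
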