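rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  # guard against numerical zeros at tiny shapes; frequencies must stay > 0
  g <- pmax(g, 1e-300)
  p <- g / sum(g)
  p <- pmax(p, 1e-12)
  p / sum(p)
}

str_allele_labels <- function(k, microvariant_rate = 0.1, start = 8L) {
  base <- seq.int(start, start + k - 1L)
  lab <- as.character(base)
  mv <- runif(k) < microvariant_rate
  lab[mv] <- paste0(base[mv], ".3")
  lab
}

#' Simulate an ancestral allele-frequency table
#'
#' Per locus, the allele count is drawn uniformly from
#' `alleles_per_locus` (default 7-16, the span typical of highly
#' polymorphic autosomal STR panels) and frequencies from a symmetric
#' Dirichlet(alpha). Allele labels are STR-like repeat numbers with
#' occasional ".3" microvariants so that fractional-label ordering is
#' exercised.
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus integer range `c(min, max)`.
#' @param dirichlet_alpha symmetric Dirichlet concentration.
#' @param n_individuals nominal sample size N (sets gene_copies = 2N).
#' @param seed integer seed (mandatory; output is reproducible).
#' @param microvariant_rate chance an allele label is a ".3" variant.
#' @param population population name.
#' @return a `freq_table`.
#' @export
simulate_ancestral_freqs <- function(n_loci = 15L,
                                     alleles_per_locus = c(7L, 16L),
                                     dirichlet_alpha = 1,
                                     n_individuals = 590L,
                                     seed,
                                     microvariant_rate = 0.1,
                                     population = "ancestral") {
  if (missing(seed)) stop("simulate_ancestral_freqs requires a seed")
  set.seed(seed)
  loci <- stats::setNames(vector("list", n_loci),
                          sprintf("L%02d", seq_len(n_loci)))
  for (i in seq_len(n_loci)) {
    kk <- alleles_per_locus[1]:alleles_per_locus[2]
    k <- if (length(kk) == 1L) kk else sample(kk, 1L)
    fr <- rdirichlet1(rep(dirichlet_alpha, k))
    names(fr) <- str_allele_labels(k, microvariant_rate)
    loci[[i]] <- fr
  }
  freq_table(population, loci, 2L * n_individuals)
}

#' Drift a population from an ancestral frequency table
#'
#' Balding-Nichols model: descendant frequencies at each locus are drawn
#' from Dirichlet(p * (1 - theta) / theta) around the ancestral vector
#' p. Each descendant frequency has expectation p_i and variance
#' theta * p_i * (1 - p_i), so theta acts as an F_ST-like divergence
#' parameter.
#'
#' @param ancestral a `freq_table`.
#' @param theta divergence parameter in \[0, 1); 0 returns a copy.
#' @param seed integer seed (mandatory).
#' @param population name of the descendant population.
#' @return a `freq_table` on the same loci and allele labels.
#' @export
diverge_population <- function(ancestral, theta, seed,
                               population = paste0(ancestral$population,
                                                   "_drift")) {
  if (missing(seed)) stop("diverge_population requires a seed")
  stopifnot(theta >= 0, theta < 1)
  set.seed(seed)
  loci <- lapply(ancestral$loci, function(fr) {
    if (theta == 0) return(fr)
    p <- rdirichlet1(fr * (1 - theta) / theta)
    names(p) <- names(fr)
    p
  })
  freq_table(population, loci, ancestral$gene_copies)
}

#' Simulate diploid genotypes at given allele frequencies
#'
#' Genotype law with inbreeding coefficient f:
#' P(homozygote ii) = p_i^2 + f p_i (1 - p_i),
#' P(heterozygote ij) = 2 p_i p_j (1 - f).
#' Implemented by drawing, per individual and locus, either one allele
#' copied twice (probability f) or two independent alleles.
#'
#' @param freqs a `freq_table`.
#' @param n_individuals number of diploid individuals.
#' @param inbreeding_f excess-homozygosity parameter in \[0, 1\].
#' @param seed integer seed (mandatory).
#' @param prefix sample-identifier prefix.
#' @return a `genotype_table`.
#' @export
simulate_genotypes <- function(freqs, n_individuals, inbreeding_f = 0,
                               seed, prefix = "S") {
  if (missing(seed)) stop("simulate_genotypes requires a seed")
  stopifnot(inbreeding_f >= 0, inbreeding_f <= 1)
  validate_freq_table(freqs)
  set.seed(seed)
  loci <- names(freqs$loci)
  n <- n_individuals
  a1 <- a2 <- matrix(NA_character_, n, length(loci))
  for (j in seq_along(loci)) {
    fr <- freqs$loci[[j]]
    p <- fr / sum(fr)
    x <- sample(names(fr), n, replace = TRUE, prob = p)
    y <- sample(names(fr), n, replace = TRUE, prob = p)
    ibd <- runif(n) < inbreeding_f
    y[ibd] <- x[ibd]
    a1[, j] <- x
    a2[, j] <- y
  }
  genotype_table(sprintf("%s%04d", prefix, seq_len(n)), loci, a1, a2)
}

#' Simulate a multi-population scenario
#'
#' One ancestral population plus `n_populations - 1` descendants diverged
#' by per-population theta values, each with its own simulated genotype
#' table; sample allele frequencies estimated from those genotypes are
#' returned alongside the true post-drift frequencies. This mirrors the
#' design of multi-group STR comparisons (a focal population plus
#' reference groups on a shared locus panel).
#'
#' @inheritParams simulate_ancestral_freqs
#' @param n_populations total number of populations.
#' @param theta divergence parameter(s) for the descendants (recycled).
#' @param inbreeding_f inbreeding coefficient for genotype simulation.
#' @param simulate_genotype_tables if `FALSE`, skip genotype drawing.
#' @return list with `freqs` (true `freq_table`s, ancestral first),
#'   `sample_freqs` (estimated from genotypes, or `NULL`), and
#'   `genotypes` (list of `genotype_table`s, or `NULL`).
#' @export
simulate_population_set <- function(n_loci = 15L, n_populations = 14L,
                                    theta = 0.05, n_individuals = 590L,
                                    alleles_per_locus = c(7L, 16L),
                                    dirichlet_alpha = 1,
                                    inbreeding_f = 0, seed,
                                    simulate_genotype_tables = TRUE) {
  if (missing(seed)) stop("simulate_population_set requires a seed")
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, 2L * n_populations)
  anc <- simulate_ancestral_freqs(n_loci, alleles_per_locus,
                                  dirichlet_alpha, n_individuals,
                                  seed = subseeds[1],
                                  population = "POP01")
  thetas <- rep_len(theta, n_populations - 1L)
  freqs <- c(list(anc), lapply(seq_len(n_populations - 1L), function(i) {
    diverge_population(anc, thetas[i], seed = subseeds[1L + i],
                       population = sprintf("POP%02d", i + 1L))
  }))
  genotypes <- sample_freqs <- NULL
  if (simulate_genotype_tables) {
    genotypes <- lapply(seq_along(freqs), function(i) {
      simulate_genotypes(freqs[[i]], n_individuals, inbreeding_f,
                         seed = subseeds[n_populations + i],
                         prefix = sprintf("P%02dS", i))
    })
    sample_freqs <- lapply(seq_along(freqs), function(i) {
      g <- genotypes[[i]]
      loci <- stats::setNames(lapply(g$loci, function(L) {
        fr <- estimate_allele_frequencies(g, L)
        attr(fr, "gene_copies") <- NULL
        fr
      }), g$loci)
      freq_table(freqs[[i]]$population, loci, 2L * n_individuals)
    })
  }
  list(freqs = freqs, sample_freqs = sample_freqs, genotypes = genotypes,
       theta = thetas)
}
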