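# Small constructors and independent oracles used across the suite.

# genotype table from per-locus allele-pair vectors:
# gt(L1 = list(c("9","11"), c("9","9")), L2 = ...)
gt <- function(...) {
  loci <- list(...)
  n <- length(loci[[1]])
  a1 <- sapply(loci, function(p) vapply(p, `[`, "", 1L))
  a2 <- sapply(loci, function(p) vapply(p, `[`, "", 2L))
  if (n == 1L) { a1 <- matrix(a1, 1L); a2 <- matrix(a2, 1L) }
  genotype_table(sprintf("S%03d", seq_len(n)), names(loci), a1, a2)
}

# Exact HWE p-value by exhaustive enumeration of all pairings of the
# labelled gene copies (each pairing equally likely under the shuffle
# null). Independent of the Monte-Carlo engine: statistic recomputed here.
hwe_stat_r <- function(x, y) {
  het <- sum(x != y)
  cls <- paste(pmin(x, y), pmax(x, y))
  het * log(2) - sum(lgamma(table(cls) + 1))
}

hwe_enum_exact <- function(a1, a2) {
  obs <- hwe_stat_r(a1, a2)
  pool <- c(a1, a2)
  stats <- numeric(0)
  pairup <- function(rest, x, y) {
    if (length(rest) == 0L) {
      stats[length(stats) + 1L] <<- hwe_stat_r(x, y)
      return(invisible())
    }
    for (i in 2:length(rest)) {
      pairup(rest[-c(1L, i)], c(x, rest[1L]), c(y, rest[i]))
    }
  }
  pairup(pool, character(0), character(0))
  mean(stats <= obs + 1e-9)
}

# closed-form biallelic r2 from phased haplotype counts
r2_closed_form <- function(n_AB, n_Ab, n_aB, n_ab) {
  n <- n_AB + n_Ab + n_aB + n_ab
  p <- (n_AB + n_Ab) / n
  q <- (n_AB + n_aB) / n
  D <- n_AB / n - p * q
  D^2 / (p * (1 - p) * q * (1 - q))
}

# orthogonal Procrustes residual (centering + best rotation/reflection)
procrustes_residual <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)
  sc <- sum(s$d) / sum(X^2)
  sqrt(sum((Y - sc * X %*% t(R))^2))
}

# does the unrooted tree contain a split separating `tips` from the rest?
has_split <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  all_tips <- attr(parts, "labels")
  target <- sort(match(tips, all_tips))
  comp <- sort(setdiff(seq_along(all_tips), target))
  any(vapply(parts, function(p) {
    identical(sort(p), target) || identical(sort(p), comp)
  }, TRUE))
}

# random additive distance matrix: path lengths on a random binary tree
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, d = cophenetic(tr)[tr$tip.label, tr$tip.label])
}
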