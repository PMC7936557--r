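#' Per-individual STR genotype table
#'
#' Stores one unordered allele pair per (sample, locus). Pairs are
#' canonicalized so that (a, b) and (b, a) are the same genotype; a call
#' with either allele missing is treated as wholly missing and excluded
#' from all counts at that locus only.
#'
#' @param samples character vector of sample identifiers.
#' @param loci character vector of locus names.
#' @param a1,a2 character matrices (samples x loci) of allele labels, `NA`
#'   for missing.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(samples, loci, a1, a2) {
  if (length(samples) < 1L) stop("genotype table needs at least one sample")
  a1 <- matrix(as.character(a1), length(samples), length(loci),
               dimnames = list(samples, loci))
  a2 <- matrix(as.character(a2), length(samples), length(loci),
               dimnames = list(samples, loci))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-called genotype(s) treated as missing")
    a1[half] <- NA_character_
    a2[half] <- NA_character_
  }
  # canonical order within the pair: smaller repeat value first
  both <- !is.na(a1)
  if (any(both)) {
    v1 <- allele_value(a1[both])
    v2 <- allele_value(a2[both])
    swap <- v1 > v2
    if (any(swap)) {
      i <- which(both)[swap]
      tmp <- a1[i]; a1[i] <- a2[i]; a2[i] <- tmp
    }
  }
  structure(list(samples = samples, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", length(x$samples), "samples x",
      length(x$loci), "loci;", sum(is.na(x$a1)), "missing calls\n")
  invisible(x)
}

#' Alleles called at one locus
#'
#' @param g a `genotype_table`.
#' @param locus locus name.
#' @return list with `a1`, `a2` (character vectors over non-missing
#'   individuals) and `n` (their count).
#' @export
locus_calls <- function(g, locus) {
  if (!locus %in% g$loci) stop("unknown locus: ", locus)
  a1 <- g$a1[, locus]
  a2 <- g$a2[, locus]
  ok <- !is.na(a1)
  list(a1 = unname(a1[ok]), a2 = unname(a2[ok]), n = sum(ok))
}

#' Read a genotype table from CSV
#'
#' Layout: a `sample` column then two columns per locus named `LOCUS.1`
#' and `LOCUS.2`. Empty cells are missing; a half-called pair is demoted
#' to missing with a warning.
#'
#' @param path CSV file path.
#' @return a `genotype_table`.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("genotype table has no samples: ", path)
  if (names(df)[1] != "sample") stop("first column must be 'sample'")
  cn <- names(df)[-1]
  loci <- unique(sub("\\.[12]$", "", cn))
  need <- c(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  if (!all(need %in% cn)) stop("each locus needs a .1 and a .2 column")
  blank <- function(v) ifelse(is.na(v) | v == "", NA_character_, v)
  a1 <- sapply(loci, function(L) blank(df[[paste0(L, ".1")]]))
  a2 <- sapply(loci, function(L) blank(df[[paste0(L, ".2")]]))
  if (nrow(df) == 1L) {  # sapply drops to vector
    a1 <- matrix(a1, 1L); a2 <- matrix(a2, 1L)
  }
  genotype_table(df$sample, loci, a1, a2)
}

#' Write a genotype table to CSV
#'
#' @param g a `genotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path) {
  df <- data.frame(sample = g$samples, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (L in g$loci) {
    df[[paste0(L, ".1")]] <- ifelse(is.na(g$a1[, L]), "", g$a1[, L])
    df[[paste0(L, ".2")]] <- ifelse(is.na(g$a2[, L]), "", g$a2[, L])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
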