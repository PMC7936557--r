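#' Population allele-frequency table
#'
#' A `freq_table` holds one population's per-locus allele frequencies along
#' with the number of gene copies (2N) they were estimated from. Frequencies
#' are stored as named numeric vectors (names = allele labels, sorted by
#' repeat value). Published tables are rounded, so per-locus sums are only
#' required to lie within `0.002 * k` of 1 for k alleles.
#'
#' @param population population name.
#' @param loci named list; each element a named numeric vector of allele
#'   frequencies for one locus.
#' @param gene_copies number of gene copies 2N (positive even integer).
#' @return object of class `freq_table`.
#' @export
freq_table <- function(population, loci, gene_copies) {
  loci <- loci[sort(names(loci))]
  loci <- lapply(loci, function(fr) fr[order(allele_value(names(fr)))])
  x <- structure(list(population = population, loci = loci,
                      gene_copies = as.integer(gene_copies)),
                 class = "freq_table")
  validate_freq_table(x)
  x
}

#' Validate a frequency table
#'
#' Checks allele-label uniqueness, frequency range (0, 1], the per-locus
#' rounding-slack sum band, and that gene copies are a positive even count.
#'
#' @param x a `freq_table`.
#' @return `x`, invisibly; errors describe the offending locus.
#' @export
validate_freq_table <- function(x) {
  stopifnot(inherits(x, "freq_table"))
  if (length(x$loci) == 0L) stop("frequency table has no loci")
  if (is.na(x$gene_copies) || x$gene_copies < 2L || x$gene_copies %% 2L != 0L)
    stop("gene_copies must be a positive even integer (2N)")
  for (loc in names(x$loci)) {
    fr <- x$loci[[loc]]
    if (anyDuplicated(names(fr)))
      stop("duplicate allele label at locus ", loc)
    if (any(fr <= 0) || any(fr > 1))
      stop("frequency outside (0, 1] at locus ", loc)
    k <- length(fr)
    s <- sum(fr)
    if (abs(s - 1) > 0.002 * k)
      stop("frequencies at locus ", loc, " sum to ", format(s),
           ", outside the rounding-slack band 1 +/- ", format(0.002 * k))
  }
  invisible(x)
}

#' @export
print.freq_table <- function(x, ...) {
  k <- vapply(x$loci, length, 1L)
  cat("Allele-frequency table:", x$population, "\n")
  cat(" ", length(x$loci), "loci,", sum(k), "alleles, 2N =",
      x$gene_copies, "\n")
  invisible(x)
}

#' Read an allele-frequency table from CSV
#'
#' Expects `#population=` and `#gene_copies=` metadata lines, any further
#' `#` comments, then a header `locus,allele,frequency` and one row per
#' allele.
#'
#' @param path CSV file path.
#' @return a validated `freq_table`.
#' @export
read_freq_table <- function(path) {
  if (!file.exists(path)) stop("frequency table not found: ", path)
  raw <- readLines(path)
  meta <- grep("^#", raw, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(m) != 1L) stop("missing #", key, "= metadata line in ", path)
    sub(paste0("^#", key, "="), "", m)
  }
  population <- get_meta("population")
  gene_copies <- as.integer(get_meta("gene_copies"))
  df <- read.csv(text = paste(raw[!grepl("^#", raw)], collapse = "\n"),
                 colClasses = c("character", "character", "numeric"))
  if (!identical(names(df), c("locus", "allele", "frequency")))
    stop("expected columns locus,allele,frequency in ", path)
  if (anyDuplicated(df[c("locus", "allele")]))
    stop("duplicate (locus, allele) row in ", path)
  loci <- lapply(split(df, df$locus), function(d) {
    fr <- d$frequency
    names(fr) <- d$allele
    fr
  })
  freq_table(population, loci, gene_copies)
}

#' Write an allele-frequency table to CSV
#'
#' @param x a `freq_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(x, path) {
  validate_freq_table(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#population=", x$population),
               paste0("#gene_copies=", x$gene_copies),
               "locus,allele,frequency"), con)
  for (loc in names(x$loci)) {
    fr <- x$loci[[loc]]
    writeLines(sprintf("%s,%s,%s", loc, names(fr),
                       formatC(fr, format = "fg", digits = 15)), con)
  }
  invisible(path)
}

#' Reconstruct integer allele counts from published frequencies
#'
#' Published tables print rounded frequencies; the underlying counts are
#' recovered as `round(p * 2N)`, floored at 1 so that every listed allele
#' keeps at least one gene copy. Per-locus count sums land within about
#' k/2 of 2N (rounding slack for k alleles).
#'
#' @param x a `freq_table`.
#' @return named list of integer count vectors, one per locus, with an
#'   attribute `"sum_deviation"` giving each locus's count-sum minus 2N.
#' @export
reconstruct_counts <- function(x) {
  validate_freq_table(x)
  counts <- lapply(x$loci, function(fr) {
    n <- pmax(1L, as.integer(round(fr * x$gene_copies)))
    names(n) <- names(fr)
    n
  })
  attr(counts, "sum_deviation") <-
    vapply(counts, sum, 1L) - x$gene_copies
  counts
}
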