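#' Counting estimate of allele frequencies at a locus
#'
#' @param g a `genotype_table`.
#' @param locus locus name.
#' @return named numeric vector of frequencies (allele count / 2n over
#'   non-missing individuals), with attribute `"gene_copies"` = 2n.
#' @export
estimate_allele_frequencies <- function(g, locus) {
  calls <- locus_calls(g, locus)
  if (calls$n == 0L) stop("all calls missing at locus ", locus)
  cnt <- table(c(calls$a1, calls$a2))
  fr <- as.numeric(cnt) / (2 * calls$n)
  names(fr) <- names(cnt)
  fr <- fr[order(allele_value(names(fr)))]
  attr(fr, "gene_copies") <- 2L * calls$n
  fr
}

#' Observed heterozygosity at a locus
#'
#' Fraction of non-missing individuals whose two alleles differ.
#'
#' @inheritParams estimate_allele_frequencies
#' @return fraction in \[0, 1\].
#' @export
observed_heterozygosity <- function(g, locus) {
  calls <- locus_calls(g, locus)
  if (calls$n == 0L) stop("all calls missing at locus ", locus)
  mean(calls$a1 != calls$a2)
}

#' Unbiased expected heterozygosity
#'
#' He = 2N/(2N - 1) * (1 - sum p_i^2), the sample-size-corrected
#' gene diversity computed on gene copies.
#'
#' @param freqs named numeric vector of allele frequencies.
#' @param gene_copies number of gene copies 2N (>= 2).
#' @return He in \[0, 1\].
#' @export
expected_heterozygosity <- function(freqs, gene_copies) {
  if (gene_copies < 2) stop("gene_copies must be at least 2")
  gene_copies / (gene_copies - 1) * (1 - sum(freqs^2))
}

#' Polymorphism information content
#'
#' PIC = 1 - sum p_i^2 - (sum p_i^2)^2 + sum p_i^4.
#'
#' @param freqs named numeric vector of allele frequencies.
#' @return PIC in \[0, 1); 0 for a monomorphic locus.
#' @export
pic <- function(freqs) {
  s2 <- sum(freqs^2)
  1 - s2 - s2^2 + sum(freqs^4)
}

#' Matching probability and power of discrimination
#'
#' MP is the sum of squared observed genotype-class frequencies (the
#' chance that two random individuals share a genotype); PD = 1 - MP.
#'
#' @inheritParams estimate_allele_frequencies
#' @return list with `mp` and `pd`.
#' @export
match_probability <- function(g, locus) {
  calls <- locus_calls(g, locus)
  if (calls$n == 0L) stop("all calls missing at locus ", locus)
  cls <- paste(calls$a1, calls$a2, sep = "/")
  mp <- sum((table(cls) / calls$n)^2)
  list(mp = mp, pd = 1 - mp)
}

#' Probability of exclusion from observed heterozygosity
#'
#' PE = h^2 (1 - 2 h H^2) with H = 1 - h, the single-locus random-man
#' exclusion probability in the PowerStats convention. Strictly
#' increasing in h on \[0, 1\].
#'
#' @param h observed heterozygosity in \[0, 1\] (vectorized).
#' @return PE in \[0, 1\].
#' @export
power_of_exclusion <- function(h) {
  stopifnot(all(h >= 0 & h <= 1))
  H <- 1 - h
  h^2 * (1 - 2 * h * H^2)
}

#' Decimal expansion of 1 - p for p very close to 0
#'
#' Combined discrimination power over many loci is 1 minus a product of
#' matching probabilities of order 1e-28, which double precision cannot
#' represent distinctly as `1 - p`. This expands `1 - p` exactly from
#' `p`'s decimal representation by digit-string subtraction, giving as
#' many significant digits as requested.
#'
#' @param p a double in \[0, 1\].
#' @param digits number of digits to keep after the decimal point.
#' @return character scalar, e.g. `"0.99999999970974..."`.
#' @export
one_minus_decimal <- function(p, digits = 45L) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0) return("1")
  if (p == 1) return("0")
  sci <- sprintf("%.17e", p)                # d.ddddddddddddddddde-XX
  mant <- sub("e.*$", "", sci)
  expo <- as.integer(sub("^.*e", "", sci))
  mdig <- as.integer(strsplit(gsub("\\.", "", mant), "")[[1]])  # 18 digits
  k <- 17L - expo                            # p = M * 10^-k, M = mdig
  if (k < length(mdig)) stop("p too close to 1 for digit expansion")
  M <- c(rep(0L, k - length(mdig)), mdig)    # k digits
  # 10^k - M = (k nines - M) + 1
  res <- 9L - M
  i <- k
  repeat {                                   # add 1 with carry
    res[i] <- res[i] + 1L
    if (res[i] < 10L) break
    res[i] <- 0L
    i <- i - 1L
    if (i == 0L) return("1")                 # p underflowed to 0
  }
  paste0("0.", paste(res[seq_len(min(k, digits))], collapse = ""))
}

#' Combined discrimination and exclusion power over loci
#'
#' CPD = 1 - prod(MP_l); CPE = 1 - prod(1 - PE_l). Because CPD is
#' conventionally reported to >30 significant digits, both are returned
#' as exact decimal strings (see [one_minus_decimal()]) alongside the
#' residual products.
#'
#' @param mp per-locus matching probabilities.
#' @param pe per-locus exclusion probabilities.
#' @return list with `cpd`, `cpe` (decimal strings), and the residuals
#'   `mp_product`, `pe_residual` (= prod(1 - PE)).
#' @export
combined_powers <- function(mp, pe) {
  if (length(mp) == 0L || length(pe) == 0L)
    stop("combined_powers needs at least one locus")
  stopifnot(all(mp >= 0 & mp <= 1), all(pe >= 0 & pe <= 1))
  mprod <- prod(mp)
  presid <- prod(1 - pe)
  list(cpd = one_minus_decimal(mprod),
       cpe = one_minus_decimal(presid),
       mp_product = mprod,
       pe_residual = presid)
}

#' Per-locus forensic summary
#'
#' Genotype mode (`g` supplied): all parameters are computed from the
#' genotype table. Frequency mode (`freqs` supplied): He and PIC come
#' from the published frequencies; PE is filled in when per-locus
#' observed heterozygosities `ho` are supplied; MP, PD and Ho need
#' genotypes and are reported `NA`.
#'
#' @param g a `genotype_table`, or `NULL`.
#' @param freqs a `freq_table`, or `NULL`.
#' @param ho optional named numeric vector of observed heterozygosities
#'   (frequency mode only).
#' @return data.frame with columns locus, n, allele_count, Ho, He, PIC,
#'   MP, PD, PE; attribute `"combined"` holds [combined_powers()] output
#'   when every locus has the needed parameters.
#' @export
forensic_summary <- function(g = NULL, freqs = NULL, ho = NULL) {
  if (is.null(g) == is.null(freqs))
    stop("supply exactly one of a genotype table or a frequency table")
  if (!is.null(g)) {
    rows <- lapply(g$loci, function(L) {
      fr <- estimate_allele_frequencies(g, L)
      n2 <- attr(fr, "gene_copies")
      h <- observed_heterozygosity(g, L)
      mpd <- match_probability(g, L)
      data.frame(locus = L, n = n2 %/% 2L, allele_count = length(fr),
                 Ho = h, He = expected_heterozygosity(fr, n2),
                 PIC = pic(fr), MP = mpd$mp, PD = mpd$pd,
                 PE = power_of_exclusion(h))
    })
    out <- do.call(rbind, rows)
    attr(out, "combined") <- combined_powers(out$MP, out$PE)
  } else {
    validate_freq_table(freqs)
    rows <- lapply(names(freqs$loci), function(L) {
      fr <- freqs$loci[[L]]
      h <- if (!is.null(ho) && L %in% names(ho)) unname(ho[L]) else NA_real_
      data.frame(locus = L, n = freqs$gene_copies %/% 2L,
                 allele_count = length(fr), Ho = h,
                 He = expected_heterozygosity(fr, freqs$gene_copies),
                 PIC = pic(fr), MP = NA_real_, PD = NA_real_,
                 PE = if (is.na(h)) NA_real_ else power_of_exclusion(h))
    })
    out <- do.call(rbind, rows)
    if (!anyNA(out$PE))
      attr(out, "combined") <- list(
        cpe = one_minus_decimal(prod(1 - out$PE)),
        pe_residual = prod(1 - out$PE))
  }
  rownames(out) <- NULL
  out
}
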