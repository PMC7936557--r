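#' Numeric value of STR allele labels
#'
#' STR alleles are named by repeat count, with microvariants written as a
#' fractional suffix ("15.3" = 15 repeats plus 3 bases). Labels compare by
#' that decimal value, so "15.3" sorts between "15" and "16".
#'
#' @param labels character vector of allele labels.
#' @return numeric vector of repeat values.
#' @export
allele_value <- function(labels) {
  v <- suppressWarnings(as.numeric(labels))
  if (anyNA(v)) {
    stop("non-numeric allele label(s): ",
         paste(unique(labels[is.na(v)]), collapse = ", "))
  }
  v
}

#' Sort allele labels by repeat value
#'
#' @param labels character vector of allele labels.
#' @return `labels` reordered by increasing numeric repeat value.
#' @export
sort_alleles <- function(labels) {
  labels[order(allele_value(labels))]
}
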