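#' Validate a labelled distance matrix
#'
#' @param m square numeric matrix with identical row/column names, exact
#'   symmetry, zero diagonal and non-negative entries.
#' @return `m`, invisibly.
#' @export
validate_distance_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("distance matrix needs matching row and column labels")
  if (!isTRUE(all.equal(m, t(m), tolerance = 0)) && !identical(m, t(m)))
    stop("distance matrix must be exactly symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  if (any(m < 0)) stop("distances must be non-negative")
  invisible(m)
}

phylip_label <- function(labels) {
  lab <- gsub("[[:space:]]+", "_", labels)
  lab <- substr(lab, 1L, 10L)
  if (anyDuplicated(lab))
    stop("labels collide after truncation to 10 characters: ",
         paste(lab[duplicated(lab)], collapse = ", "))
  formatC(lab, width = -10)
}

#' Write a distance matrix (PHYLIP square or CSV)
#'
#' The PHYLIP square dialect has the taxon count on the first line, then
#' one row per taxon: the label padded to 10 characters followed by the
#' full row of distances. Labels longer than 10 characters are truncated;
#' a collision after truncation is an error.
#'
#' @param m labelled symmetric distance matrix.
#' @param path output path.
#' @param format `"phylip"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path, format = c("phylip", "csv")) {
  format <- match.arg(format)
  validate_distance_matrix(m)
  if (format == "csv") {
    write.csv(as.data.frame(m), path, quote = FALSE)
  } else {
    lab <- phylip_label(rownames(m))
    rows <- vapply(seq_len(nrow(m)), function(i) {
      paste0(lab[i], paste(sprintf("%.6f", m[i, ]), collapse = "  "))
    }, "")
    writeLines(c(sprintf("%5d", nrow(m)), rows), path)
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path file path.
#' @param format `"phylip"` or `"csv"`.
#' @return labelled symmetric matrix.
#' @export
read_distance_matrix <- function(path, format = c("phylip", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  } else {
    raw <- readLines(path)
    n <- as.integer(trimws(raw[1]))
    lab <- trimws(substr(raw[2:(n + 1)], 1L, 10L))
    vals <- lapply(raw[2:(n + 1)], function(l)
      as.numeric(strsplit(trimws(substring(l, 11L)), "[[:space:]]+")[[1]]))
    m <- do.call(rbind, vals)
    dimnames(m) <- list(lab, lab)
  }
  m <- (m + t(m)) / 2  # absorb print rounding asymmetry
  diag(m) <- 0
  validate_distance_matrix(m)
  m
}
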