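#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes, and
#' returns the leading eigenvector coordinates scaled by the square root
#' of their eigenvalues (via [stats::cmdscale()]). Negative eigenvalues
#' (non-Euclidean input) are truncated to zero; their total magnitude is
#' reported. When the input is the distance matrix of a d-dimensional
#' Euclidean configuration, the first d coordinates reproduce it up to
#' rotation, reflection and translation.
#'
#' @param m labelled symmetric distance matrix, n >= 3 for 2 dimensions.
#' @param dims number of output dimensions (< n).
#' @return list of class `strp_ordination`: `labels`, `coords`
#'   (n x dims), `explained` (all eigenvalues, negatives truncated to 0,
#'   non-increasing), `negative_inertia` (sum of |negative eigenvalues|).
#' @export
classical_mds <- function(m, dims = 2L) {
  validate_distance_matrix(m)
  n <- nrow(m)
  if (dims >= n) stop("dims must be smaller than the number of points")
  fit <- suppressWarnings(cmdscale(m, k = n - 1, eig = TRUE))
  eig <- fit$eig
  neg <- sum(abs(eig[eig < 0]))
  coords <- matrix(0, n, dims, dimnames = list(rownames(m), NULL))
  have <- min(dims, ncol(fit$points))
  if (have > 0) coords[, seq_len(have)] <- fit$points[, seq_len(have)]
  structure(list(labels = rownames(m), coords = coords,
                 explained = pmax(eig, 0), negative_inertia = neg,
                 method = "classical_mds"),
            class = "strp_ordination")
}

#' Population x (locus, allele) frequency matrix
#'
#' One row per population; columns are the union allele space of each
#' panel locus, absent alleles at frequency 0.
#'
#' @param pops list of `freq_table` objects.
#' @param loci locus panel; defaults to the shared panel.
#' @return numeric matrix with `population` rownames and
#'   `locus.allele` colnames.
#' @export
frequency_matrix <- function(pops, loci = NULL) {
  if (is.null(loci)) loci <- shared_loci(pops)
  if (length(loci) == 0L) stop("no loci shared by all populations")
  cols <- lapply(loci, function(L) {
    alleles <- sort_alleles(unique(unlist(
      lapply(pops, function(p) names(p$loci[[L]])))))
    sub <- vapply(pops, function(p) {
      v <- p$loci[[L]][alleles]
      v[is.na(v)] <- 0
      v
    }, numeric(length(alleles)))
    sub <- matrix(sub, nrow = length(alleles))
    rownames(sub) <- paste(L, alleles, sep = ".")
    t(sub)
  })
  m <- do.call(cbind, cols)
  rownames(m) <- vapply(pops, function(p) p$population, "")
  m
}

#' PCA of population allele-frequency vectors
#'
#' Covariance PCA (columns centered, not scaled — frequencies share a
#' scale) of the [frequency_matrix()]. At most
#' min(populations - 1, features) components carry variance.
#'
#' @param pops list of `freq_table` objects (>= 3).
#' @param dims number of component coordinates to return.
#' @param loci locus panel; defaults to the shared panel.
#' @return `strp_ordination` whose `explained` holds per-component
#'   variance fractions (non-increasing, summing to 1 over all
#'   components); extra fields `rotation` and `center` allow exact
#'   reconstruction of the centered data.
#' @export
pca_frequencies <- function(pops, dims = 3L, loci = NULL) {
  if (length(pops) < 3L) stop("PCA needs at least 3 populations")
  m <- frequency_matrix(pops, loci)
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  v <- fit$sdev^2
  dims <- min(dims, ncol(fit$x))
  structure(list(labels = rownames(m),
                 coords = fit$x[, seq_len(dims), drop = FALSE],
                 explained = v / sum(v),
                 scores = fit$x, rotation = fit$rotation,
                 center = fit$center, method = "pca"),
            class = "strp_ordination")
}

#' @export
print.strp_ordination <- function(x, ...) {
  cat(x$method, "over", length(x$labels), "populations;",
      ncol(x$coords), "coordinate dimension(s)\n")
  ex <- x$explained[seq_len(min(3, length(x$explained)))]
  cat("  leading explained:", paste(signif(ex, 4), collapse = ", "), "\n")
  invisible(x)
}
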