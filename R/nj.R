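#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler criterion
#' Q(i,j) = (n-2) d(i,j) - R_i - R_j, where R is the row sum over active
#' clusters. The pair minimizing Q is joined; ties resolve to the lowest
#' (row, column) index pair in the current cluster order, so the result is
#' deterministic. Branch lengths use
#' v_i = d(i,j)/2 + (R_i - R_j)/(2(n-2)); negative lengths are clamped to
#' zero and the clamped magnitude is reported via the `"clamped"`
#' attribute (the conventional display rule). On an additive matrix the
#' leaf-to-leaf path lengths reproduce the input exactly.
#'
#' The unrooted tree is serialized with a trifurcation at the final join
#' (two leaves give a midpoint split).
#'
#' @param m labelled symmetric distance matrix, n >= 2.
#' @return an [ape::read.tree()] `phylo` object; attribute `"clamped"`
#'   holds the total negative length removed.
#' @export
neighbor_joining <- function(m) {
  validate_distance_matrix(m)
  n <- nrow(m)
  if (n < 2L) stop("neighbor joining needs at least 2 taxa")
  lab <- gsub("[[:space:]]+", "_", rownames(m))
  fmt <- function(x) sprintf("%.12g", x)
  clamped <- 0
  clamp <- function(v) {
    if (v < 0) {
      clamped <<- clamped + abs(v)
      0
    } else v
  }
  if (n == 2L) {
    h <- clamp(m[1, 2] / 2)
    nwk <- paste0("(", lab[1], ":", fmt(h), ",", lab[2], ":", fmt(h), ");")
  } else {
    sub <- lab
    d <- m
    while (length(sub) > 3L) {
      nn <- length(sub)
      R <- rowSums(d)
      q <- (nn - 2) * d - outer(R, R, "+")
      diag(q) <- Inf
      # lowest (row, col) pair among minima, current order
      idx <- which(q == min(q), arr.ind = TRUE)
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      i <- idx[1, 1]; j <- idx[1, 2]
      vi <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (nn - 2)))
      vj <- clamp(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (nn - 2))))
      merged <- paste0("(", sub[i], ":", fmt(vi), ",",
                       sub[j], ":", fmt(vj), ")")
      dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
      keep <- setdiff(seq_len(nn), c(i, j))
      d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                 c(dn[keep], 0))
      sub <- c(sub[keep], merged)
    }
    v1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
    v2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
    v3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    nwk <- paste0("(", sub[1], ":", fmt(v1), ",", sub[2], ":", fmt(v2),
                  ",", sub[3], ":", fmt(v3), ");")
  }
  tree <- ape::read.tree(text = nwk)
  if (clamped > 0)
    message("neighbor_joining: clamped ", fmt(clamped),
            " of negative branch length to 0")
  attr(tree, "clamped") <- clamped
  tree
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path file path.
#' @return a `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
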