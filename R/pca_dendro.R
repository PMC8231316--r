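#' Principal component analysis of a dosage matrix
#'
#' Column-centres the dosage matrix and eigendecomposes its sample
#' covariance (via SVD). Components are ordered by decreasing explained
#' variance, and the sign of each component is fixed so that its
#' largest-magnitude loading is positive, making results deterministic.
#'
#' @param X complete numeric samples x loci matrix or complete
#'   [genotype_matrix()].
#' @param n_components number of components to keep (default: all).
#' @return object of class `snp_pca`: `scores` (samples x components),
#'   `loadings`, `explained` (variance fractions, descending), `sdev`.
#' @export
snp_pca <- function(X, n_components = NULL) {
  if (is_genotype_matrix(X)) X <- X$calls
  X <- as.matrix(X)
  if (anyNA(X)) stop("snp_pca needs a complete matrix; impute first")
  if (nrow(X) < 2) stop("PCA needs at least 2 samples")
  if (all(apply(X, 2, function(col) max(col) == min(col)))) {
    stop("zero-variance matrix: every locus is constant")
  }
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    v <- pr$rotation[, j]
    v[which.max(abs(v))] < 0
  }, logical(1))
  pr$rotation[, flip] <- -pr$rotation[, flip]
  pr$x[, flip] <- -pr$x[, flip]
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  k <- if (is.null(n_components)) ncol(pr$x) else min(n_components, ncol(pr$x))
  structure(list(scores = pr$x[, seq_len(k), drop = FALSE],
                 loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 explained = expl[seq_len(k)], sdev = pr$sdev[seq_len(k)]),
            class = "snp_pca")
}

#' @export
print.snp_pca <- function(x, ...) {
  cat("snp_pca:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * head(x$explained, 5)), collapse = ", "),
      if (length(x$explained) > 5) "..." else "", "\n")
  invisible(x)
}

#' Complete-linkage dendrogram in principal-component space
#'
#' Agglomerative hierarchical clustering of the samples on Euclidean
#' distances computed from the leading principal components (3 by default,
#' the number usually plotted), with complete linkage: the distance between
#' two clusters is the maximum pairwise distance between their members.
#'
#' @param pc a [snp_pca()] result.
#' @param n_components number of leading components to use (default 3,
#'   capped at the available components).
#' @param linkage agglomeration method, default `"complete"`.
#' @return object of class `pc_dendrogram`: the `hclust` tree, the
#'   [ape::phylo] version, and the Newick string (`newick`).
#' @export
pc_dendrogram <- function(pc, n_components = 3, linkage = "complete") {
  stopifnot(inherits(pc, "snp_pca"))
  if (nrow(pc$scores) < 2) stop("dendrogram needs at least 2 samples")
  if (n_components > ncol(pc$scores)) {
    stop("n_components exceeds the available components")
  }
  d <- dist(pc$scores[, seq_len(n_components), drop = FALSE])
  tree_from_dist(d, linkage)
}

# shared tree builder, also used directly in tests with hand-made distances
tree_from_dist <- function(d, linkage = "complete") {
  hc <- hclust(as.dist(d), method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy)),
            class = "pc_dendrogram")
}

#' @export
print.pc_dendrogram <- function(x, ...) {
  cat("pc_dendrogram:", length(x$hclust$labels), "leaves,",
      x$hclust$method, "linkage\n")
  invisible(x)
}

#' Write a dendrogram as a Newick file
#'
#' @param dnd a [pc_dendrogram()].
#' @param path output path.
#' @export
write_newick <- function(dnd, path) {
  stopifnot(inherits(dnd, "pc_dendrogram"))
  ape::write.tree(dnd$phylo, file = path)
  invisible(path)
}
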