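# Hierarchical clustering for heat-map ordering: 1 - Pearson correlation
# distance with average linkage (UPGMA), the parameters used for the
# published gene trees. Gene-axis profiles are log2-transformed and
# per-gene standardized (the relative red/green heat-map convention);
# the sample axis uses raw log2 profiles.

#' Cluster genes or samples of a signal matrix
#'
#' @param signals Gene-level [expr_matrix()] or a plain numeric matrix
#'   (rows = genes, columns = samples).
#' @param axis `"genes"` or `"samples"`.
#' @param standardize Center and scale each gene's log2 profile before
#'   correlation (default `TRUE` for the gene axis, `FALSE` for samples).
#' @return Object of class `cluster_tree`: `hclust` (the merge history),
#'   `labels`, `order` (leaf order), `dropped` (zero-variance items
#'   removed before clustering).
#' @export
cluster_profiles <- function(signals, axis = c("genes", "samples"),
                             standardize = NULL) {
  axis <- match.arg(axis)
  if (inherits(signals, "expr_matrix")) {
    mat <- signals$values
    rownames(mat) <- signals$feature_ids
  } else {
    mat <- as.matrix(signals)
    if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  }
  if (is.null(standardize)) standardize <- axis == "genes"
  x <- log2(pmax(mat, .Machine$double.xmin))
  if (axis == "samples") x <- t(x)
  if (standardize) {
    mu <- rowMeans(x)
    s <- apply(x, 1, stats::sd)
    x <- (x - mu) / ifelse(s > 0, s, 1)
  }
  v <- apply(x, 1, stats::var)
  keep <- v > 0
  dropped <- rownames(x)[!keep]
  if (length(dropped) > 0) {
    warning(length(dropped), " zero-variance item(s) dropped before correlation")
  }
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2) stop("fewer than 2 items to cluster after filtering")
  d <- stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, labels = hc$labels, order = hc$order,
                 dropped = dropped, axis = axis),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree (%s axis): %d leaves, %d merges\n",
              x$axis, length(x$labels), nrow(x$hclust$merge)))
  invisible(x)
}

#' Leaf order of a cluster tree for heat-map display
#'
#' @param tree A `cluster_tree`.
#' @return Character vector: the tree's leaf labels in dendrogram order
#'   (every subtree occupies a contiguous stretch).
#' @export
heatmap_order <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  tree$labels[tree$order]
}

#' Export a cluster tree as a Newick string
#'
#' Branch lengths carry the merge heights, so the tree can be re-imported
#' by any standard phylogenetics reader.
#'
#' @param tree A `cluster_tree`.
#' @param path Optional file path; when given the tree is written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
tree_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Do the members of each group form contiguous leaf blocks?
#'
#' Convenience check used to verify that, e.g., the three replicates of
#' each condition cluster together on the sample axis.
#'
#' @param tree A `cluster_tree`.
#' @param groups Named list: group label -> member labels.
#' @return Named logical vector, one entry per group.
#' @export
groups_contiguous <- function(tree, groups) {
  ord <- heatmap_order(tree)
  vapply(groups, function(members) {
    pos <- sort(match(members, ord))
    if (any(is.na(pos))) return(FALSE)
    all(diff(pos) == 1)
  }, logical(1))
}
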