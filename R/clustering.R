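#' Pearson correlation distance between knockout profiles
#'
#' \eqn{d = 1 - r} with r the Pearson correlation of the two binary affected
#' vectors, so identical non-constant profiles have distance 0 and perfectly
#' complementary profiles have distance 2. Correlation is undefined for a
#' zero-variance (all-affected or all-unaffected) profile; the documented
#' fallback assigns distance 0 to two identical constant vectors and 1
#' otherwise, which keeps identical rows merging at height zero. A scaled
#' variant (1 - r)/2 is available; it is a monotone rescaling, so tree
#' topology is unchanged.
#'
#' @param a,b numeric vectors of equal length >= 2
#' @param scale "raw" for 1 - r (default) or "half" for (1 - r)/2
#' @return non-negative distance
#' @export
pearson_distance <- function(a, b, scale = c("raw", "half")) {
  scale <- match.arg(scale)
  if (length(a) != length(b) || length(a) < 2L) {
    .stopf("profiles must share a length of at least 2")
  }
  va <- stats::var(a) > 0
  vb <- stats::var(b) > 0
  d <- if (va && vb) {
    1 - stats::cor(a, b)
  } else if (!va && !vb && all(a == b)) 0 else 1
  if (scale == "half") d <- d / 2
  d
}

#' Pairwise Pearson distance matrix of knockout profiles
#'
#' @param profiles numeric matrix, one row per experiment (e.g. the `affected`
#'   component of a [knockout_matrix()])
#' @param scale see [pearson_distance()]
#' @return symmetric distance matrix with zero diagonal
#' @export
pearson_distance_matrix <- function(profiles, scale = c("raw", "half")) {
  scale <- match.arg(scale)
  profiles <- as.matrix(profiles) * 1
  n <- nrow(profiles)
  D <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- pearson_distance(profiles[i, ], profiles[j, ], scale)
    }
  }
  D
}

#' UPGMA cluster tree of knockout profiles
#'
#' Standard unweighted pair-group average linkage: the closest pair of
#' clusters merges, and distances to the merged cluster are the
#' cluster-size-weighted arithmetic means of the member distances. Merge
#' heights follow the d/2 convention (the height of a merge at distance d is
#' d/2), giving an ultrametric tree. Tie-breaking is deterministic: among
#' equal minimal distances the lexicographically smallest label pair merges
#' first (labels are pre-sorted, so the underlying `stats::hclust` average
#' linkage resolves ties in that order).
#'
#' @param distances symmetric numeric matrix with zero diagonal and labelled
#'   rows/columns
#' @param labels optional label vector overriding the matrix dimnames
#' @return object of class `cluster_tree` wrapping an `hclust` object with
#'   components `merge`, `height` (d/2 scale), `labels`
#' @export
upgma <- function(distances, labels = NULL) {
  distances <- as.matrix(distances)
  if (!is.null(labels)) dimnames(distances) <- list(labels, labels)
  if (is.null(rownames(distances))) {
    dimnames(distances) <- list(seq_len(nrow(distances)), seq_len(nrow(distances)))
  }
  if (nrow(distances) != ncol(distances) ||
      any(abs(distances - t(distances)) > 1e-12)) {
    .stopf("distance matrix must be symmetric")
  }
  if (any(diag(distances) != 0)) .stopf("distance matrix must have a zero diagonal")
  ord <- .id_order(rownames(distances))
  distances <- distances[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(distances), method = "average")
  hc$height <- hc$height / 2
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 labels = hc$labels), class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, root height %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Convert a cluster tree to an ape phylo object
#'
#' Branch lengths are height differences between parent and child merges, so
#' leaf-to-root path lengths equal the root height (ultrametric).
#'
#' @param tree a `cluster_tree`
#' @return an `ape::phylo`
#' @export
as_phylo <- function(tree) {
  ape::as.phylo(tree$hclust)
}

#' Write a cluster tree in Newick format
#'
#' @param tree a `cluster_tree`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}

#' Annotate internal nodes that cover a single process
#'
#' An internal node inherits a process label (e.g. apoptosis, necroptosis,
#' NF-kB activation) when all its descendant leaves carry that same label;
#' mixed subtrees stay unlabelled.
#'
#' @param tree a `cluster_tree`
#' @param annotation named character vector mapping leaf labels to processes
#' @return the tree with a `node_labels` component: one label (or NA) per
#'   internal node, in `merge` row order
#' @export
tree_labels <- function(tree, annotation) {
  unknown <- setdiff(names(annotation), tree$labels)
  if (length(unknown)) .stopf("annotation references unknown leaves: %s",
                              paste(unknown, collapse = ", "))
  n_int <- nrow(tree$merge)
  node_lab <- rep(NA_character_, n_int)
  leaf_sets <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    kids <- tree$merge[i, ]
    leaves <- unlist(lapply(kids, function(k)
      if (k < 0) tree$labels[-k] else leaf_sets[[k]]))
    leaf_sets[[i]] <- leaves
    labs <- unique(annotation[leaves])
    if (length(labs) == 1L && !is.na(labs) && all(leaves %in% names(annotation))) {
      node_lab[i] <- labs
    }
  }
  tree$node_labels <- node_lab
  tree
}

#' Export a distance matrix as TSV
#'
#' @param distances symmetric matrix
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_distance_tsv <- function(distances, path) {
  df <- data.frame(label = rownames(distances), distances, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
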