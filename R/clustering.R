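# Average-linkage clustering of the focus set, minimal partition under the
# intra-cluster distance criterion, and medoid extraction.

validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square matrix")
  }
  if (is.null(rownames(D))) {
    dimnames(D) <- list(paste0("s", seq_len(nrow(D))),
                        paste0("s", seq_len(nrow(D))))
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("D must be symmetric")
  }
  if (any(D < 0)) stop("D must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  D
}

#' Average-linkage merge tree
#'
#' Unweighted average-linkage (UPGMA-style) hierarchical clustering of a
#' symmetric distance matrix, via [stats::hclust()]. The returned tree has
#' `n - 1` merges with non-decreasing heights.
#'
#' @param D Symmetric distance matrix with zero diagonal (dimnames used as
#'   ids; generated if absent).
#' @return List of class `linkage_tree` with `hclust` (the fitted tree),
#'   `merges` (data.frame: `i`, `j`, `height` in [stats::hclust()] merge
#'   encoding) and `ids`.
#' @export
average_linkage_tree <- function(D) {
  D <- validate_distance_matrix(D)
  hc <- hclust(as.dist(D), method = "average")
  structure(
    list(hclust = hc,
         merges = data.frame(i = hc$merge[, 1], j = hc$merge[, 2],
                             height = hc$height),
         ids = rownames(D)),
    class = "linkage_tree"
  )
}

#' Minimal partition under an intra-cluster distance criterion
#'
#' Scans k = 1, 2, ... flat partitions of the merge tree (obtained by
#' undoing the last k - 1 merges) and returns the first k for which every
#' within-cluster pairwise distance is strictly below the threshold. Since
#' k = n always satisfies the criterion, a partition always exists.
#'
#' @param tree A [average_linkage_tree()] result.
#' @param D The distance matrix the tree was built from.
#' @param threshold Intra-cluster distance criterion (default 0.6; strict
#'   `<`, boundary equality counts as a violation).
#' @return A `cluster_partition`: `labels` (named integer vector, ids ->
#'   1..N), `n_clusters`, `medoid_ids`, `max_intra`, `threshold`.
#' @export
optimal_partition <- function(tree, D, threshold = 0.6) {
  stopifnot(inherits(tree, "linkage_tree"))
  D <- validate_distance_matrix(D)
  n <- length(tree$ids)
  for (k in seq_len(n)) {
    labels <- cutree(tree$hclust, k = k)
    mi <- max_intra_distance(labels, D)
    if (mi < threshold) {
      part <- structure(
        list(labels = labels, n_clusters = k, medoid_ids = NULL,
             max_intra = mi, threshold = threshold),
        class = "cluster_partition"
      )
      part$medoid_ids <- cluster_medoids(part, D)
      return(part)
    }
  }
  stop("unreachable: the all-singletons partition satisfies any threshold")
}

max_intra_distance <- function(labels, D) {
  mi <- 0
  for (cl in unique(labels)) {
    members <- names(labels)[labels == cl]
    if (length(members) > 1L) {
      sub <- D[members, members]
      mi <- max(mi, max(sub[upper.tri(sub)]))
    }
  }
  mi
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("<cluster_partition> ", x$n_clusters, " clusters over ",
      length(x$labels), " domains; max intra-cluster distance ",
      signif(x$max_intra, 4), " (criterion < ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Cluster medoids
#'
#' Per cluster, the member minimizing the total distance to its co-members
#' (min-sum objective); ties go to the lexicographically smallest id;
#' singletons are their own medoid.
#'
#' @param partition A `cluster_partition` (or a named integer label vector).
#' @param D Distance matrix covering all labelled ids.
#' @return Character vector of medoid ids, one per cluster, in cluster-index
#'   order.
#' @export
cluster_medoids <- function(partition, D) {
  labels <- if (inherits(partition, "cluster_partition")) partition$labels else partition
  D <- validate_distance_matrix(D)
  vapply(sort(unique(labels)), function(cl) {
    members <- sort(names(labels)[labels == cl])
    if (length(members) == 1L) return(members)
    sums <- rowSums(D[members, members, drop = FALSE])
    members[which.min(sums)]  # which.min takes the first, i.e. smallest id
  }, character(1))
}

#' Between-cluster separation statistics
#'
#' Counts unordered pairs of domains in different clusters that lie closer
#' than a probe cutoff, and the fraction of all inter-cluster pairs they
#' represent. With a single cluster there are no inter-cluster pairs; the
#' fraction is reported as 0 with `zero_denominator = TRUE`.
#'
#' @param partition A `cluster_partition` (or named label vector).
#' @param D Distance matrix.
#' @param probe_cutoff Distance below which an inter-cluster pair counts
#'   (default 0.4).
#' @return List with `count`, `fraction`, `n_inter_pairs`,
#'   `zero_denominator`.
#' @export
separation_stats <- function(partition, D, probe_cutoff = 0.4) {
  labels <- if (inherits(partition, "cluster_partition")) partition$labels else partition
  D <- validate_distance_matrix(D)
  ids <- names(labels)
  ut <- which(upper.tri(D[ids, ids]), arr.ind = TRUE)
  inter <- labels[ids[ut[, 1]]] != labels[ids[ut[, 2]]]
  n_inter <- sum(inter)
  cnt <- sum(inter & D[ids, ids][upper.tri(D[ids, ids])] < probe_cutoff)
  list(count = cnt,
       fraction = if (n_inter == 0L) 0 else cnt / n_inter,
       n_inter_pairs = n_inter,
       zero_denominator = n_inter == 0L)
}

#' Write a cluster assignment TSV and the merge tree in Newick
#'
#' @param partition A `cluster_partition`.
#' @param tree The [average_linkage_tree()] the partition came from.
#' @param file Path for the assignment TSV (`id`, `cluster`, `is_medoid`).
#' @param newick_file Optional path for the dendrogram in Newick format
#'   (branch lengths from merge heights, via \pkg{ape}).
#' @return Invisibly, `file`.
#' @export
write_clusters <- function(partition, tree, file, newick_file = NULL) {
  df <- data.frame(id = names(partition$labels),
                   cluster = unname(partition$labels))
  df$is_medoid <- df$id %in% partition$medoid_ids
  write.table(df[order(df$cluster, df$id), ], file = file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(newick_file)) {
    ape::write.tree(ape::as.phylo(tree$hclust), file = newick_file)
  }
  invisible(file)
}
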