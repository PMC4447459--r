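#' Kendall-tau distance matrix between sample profiles
#'
#' Computes pairwise Kendall tau-b correlations `S` between the sample
#' expression profiles (typically restricted to the HI probes) and converts
#' them to the distance `D = (1 - S) / 2`, which lies in \[0, 1\].  Being
#' rank-based, `D` is invariant under any strictly increasing transformation
#' applied to a sample's profile.
#'
#' @param expr an `ExpressionMatrix` with at least 2 probes.
#' @return A symmetric sample x sample distance matrix with zero diagonal.
#' @export
kendall_distance_matrix <- function(expr) {
  if (nrow(expr$values) < 2)
    stop("at least 2 probes are needed for Kendall correlation")
  const <- apply(expr$values, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    stop("constant expression profile for sample(s): ",
         paste(colnames(expr$values)[const], collapse = ", "))
  S <- stats::cor(expr$values, method = "kendall")
  D <- (1 - S) / 2
  diag(D) <- 0
  D
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering (complete linkage by default) with flat labels
#' from cutting the tree into `k` clusters, plus the dendrogram leaf order
#' used for heatmap display.
#'
#' @param D symmetric distance matrix with sample IDs as dimnames.
#' @param k number of flat clusters, `1 <= k <= N`.
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return An object of class `"hclust_cut"`: list with `tree` (an
#'   [stats::hclust] object), `labels` (named integer cluster labels),
#'   `leaf_order` (sample IDs in dendrogram order), `k`, `linkage`.
#' @export
hierarchical_cluster <- function(D, k,
                                 linkage = c("complete", "average",
                                             "single")) {
  linkage <- match.arg(linkage)
  n <- nrow(D)
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples")
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  labels <- stats::cutree(tree, k = k)
  structure(list(tree = tree, labels = labels,
                 leaf_order = tree$labels[tree$order],
                 k = k, linkage = linkage),
            class = "hclust_cut")
}

#' @export
print.hclust_cut <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (%s linkage), k = %d: sizes %s\n",
              x$linkage, x$k, paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' @export
plot.hclust_cut <- function(x, ...) {
  graphics::plot(x$tree, ...)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model:
#' `ARI = (Index - E[Index]) / (Max - E[Index])` computed from the
#' contingency table of the two label vectors.  The degenerate case where
#' both partitions are a single cluster returns 1.
#'
#' @param labels_a,labels_b label vectors over the same samples.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions cover different sample universes")
  tab <- table(labels_a, labels_b)
  if (nrow(tab) == 1 && ncol(tab) == 1) return(1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(length(labels_a), 2)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
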