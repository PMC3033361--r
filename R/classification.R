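#' Pairwise geodesic distance matrix
#'
#' Computes the geodesic shape distance for every unordered pair of curves
#' and returns a labelled symmetric matrix with zero diagonal. Each pair
#' is evaluated independently, so the result does not depend on evaluation
#' order; both alignment directions are optimized per pair and the smaller
#' upper bound is kept (see [geodesic_distance()]).
#'
#' @param curves list of [backbone_curve()] objects (>= 2), ideally named.
#' @param grid_size common matching grid size.
#' @param K maximum DP lattice slope.
#' @return object of class `dist_matrix`: the n x n matrix with a
#'   `labels` attribute.
#' @export
pairwise_distances <- function(curves, grid_size = 100L, K = 4L) {
  n <- length(curves)
  if (n < 2L) stop("need at least 2 curves")
  stopifnot(all(vapply(curves, inherits, logical(1), "backbone_curve")))
  labels <- names(curves)
  if (is.null(labels)) labels <- vapply(curves, `[[`, character(1), "label")
  qs <- lapply(curves, prepare_srvf, grid_size = grid_size)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- esaprot_theta_sym(qs[[i]], qs[[j]], K)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  structure(D, class = c("dist_matrix", "matrix"), labels = labels)
}

esaprot_theta_sym <- function(qa, qb, K = 4L) theta_min_sym(qa, qb, K = K)

#' Cut an average-linkage hierarchical clustering at k clusters
#'
#' Agglomerative clustering (UPGMA / average linkage) of a symmetric
#' distance matrix, cut to exactly `n_clusters` groups. Deterministic for
#' a given matrix.
#'
#' @param D symmetric distance matrix (e.g. from [pairwise_distances()]).
#' @param n_clusters number of clusters, between 1 and n.
#' @return integer vector of cluster labels, named by the matrix labels.
#' @export
cluster_shapes <- function(D, n_clusters) {
  D <- unclass(as.matrix(D))
  n <- nrow(D)
  if (n_clusters < 1 || n_clusters > n)
    stop(sprintf("n_clusters must be in 1..%d", n))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(!is.finite(D))) stop("distance matrix has missing entries (strict mode)")
  hc <- hclust(stats::as.dist(D), method = "average")
  cutree(hc, k = n_clusters)
}

#' Rand index between two partitions
#'
#' Scores a predicted partition against reference labels over all
#' unordered item pairs: TP pairs share a class in both partitions, TN in
#' neither, FP only in the prediction, FN only in the reference. The Rand
#' index is (TP + TN) / (TP + TN + FP + FN), the fraction of pairwise
#' decisions that agree; it is invariant to relabeling of cluster ids.
#'
#' @param pred predicted cluster labels.
#' @param truth reference class labels of the same length.
#' @return object of class `partition_score`: list with `TP`, `TN`, `FP`,
#'   `FN`, `RI`.
#' @export
rand_index <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  n <- length(pred)
  if (n < 2L) stop("need at least 2 items")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same_pred <- pred[idx[, 1]] == pred[idx[, 2]]
  same_truth <- truth[idx[, 1]] == truth[idx[, 2]]
  TP <- sum(same_pred & same_truth)
  TN <- sum(!same_pred & !same_truth)
  FP <- sum(same_pred & !same_truth)
  FN <- sum(!same_pred & same_truth)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 RI = (TP + TN) / (TP + TN + FP + FN)),
            class = "partition_score")
}

#' @export
print.partition_score <- function(x, ...) {
  cat(sprintf("<partition_score: TP %d, TN %d, FP %d, FN %d, RI %.4f>\n",
              x$TP, x$TN, x$FP, x$FN, x$RI))
  invisible(x)
}
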