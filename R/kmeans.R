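# Lloyd k-means with the exact semantics the feature-clustering step
# relies on: initialization by sampling K distinct data points, Euclidean
# nearest-centroid assignment with ties broken toward the lowest cluster
# id, mean-update, reseeding of emptied clusters with the point farthest
# from their centroid, and best-of-restarts selection by WCSS. These
# deterministic tie/reseed rules (and the per-iteration WCSS trace used to
# assert monotone descent) are part of the method contract, which is why
# the algorithm is implemented here rather than delegated.

#' Lloyd k-means with restarts
#'
#' Minimizes the within-cluster sum of squares (WCSS)
#' `sum_i sum_{x in S_i} ||x - mu_i||^2` by alternating nearest-centroid
#' assignment (Euclidean distance) and centroid mean updates. Each restart
#' initializes the centroids by sampling `k` distinct data points; the
#' best restart by final WCSS wins (ties to the earlier restart).
#' Assignment ties go to the lowest cluster id; a cluster emptied during
#' assignment is reseeded with the point farthest from its centroid.
#' Iteration stops when the largest centroid shift drops below `tol` or
#' after `max_iter` iterations.
#'
#' @param x Numeric matrix of points (rows).
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param n_restarts Number of random initializations (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Centroid-shift convergence threshold (default 1e-6).
#' @param seed Optional integer seed; restart `r` uses `seed + r - 1`.
#' @return Object of class `cb_kmeans`: list with `cluster` (integer
#'   assignment 1..k per row), `centroids` (k x p matrix), `wcss`,
#'   `n_iterations`, `wcss_trace` (per-iteration WCSS of the winning
#'   restart), `wcss_per_restart`, and `restart_seed`.
#' @export
cb_kmeans <- function(x, k, n_restarts = 10L, max_iter = 300L,
                      tol = 1e-6, seed = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop("k (", k, ") exceeds number of points (", n, ")")
  if (n_restarts < 1L) stop("n_restarts must be at least 1")

  best <- NULL
  wcss_per_restart <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    rseed <- if (is.null(seed)) NULL else as.integer(seed + r - 1L)
    fit <- lloyd_once(x, k, max_iter, tol, rseed)
    wcss_per_restart[r] <- fit$wcss
    if (is.null(best) || fit$wcss < best$wcss) {
      best <- fit
      best$restart_seed <- rseed
    }
  }
  best$wcss_per_restart <- wcss_per_restart
  class(best) <- "cb_kmeans"
  best
}

lloyd_once <- function(x, k, max_iter, tol, seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  centroids <- x[sample.int(n, k), , drop = FALSE]
  xx <- rowSums(x^2)
  wcss_trace <- numeric(0)
  assign <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # squared Euclidean distances, n x k
    d2 <- xx - 2 * x %*% t(centroids) +
      rep(rowSums(centroids^2), each = n)
    d2[d2 < 0] <- 0
    # ties.method = "first" on -d2 picks the lowest cluster id among ties
    assign <- max.col(-d2, ties.method = "first")
    # reseed emptied clusters with the point farthest from their centroid;
    # iterate because reseeding must never empty a donor cluster, so only
    # points from clusters of size >= 2 may move
    n_reseeds <- 0L
    repeat {
      sizes <- tabulate(assign, nbins = k)
      e <- which(sizes == 0L)[1]
      if (is.na(e)) break
      movable <- sizes[assign] >= 2L
      cand <- which(movable)[which.max(d2[movable, e])]
      assign[cand] <- e
      n_reseeds <- n_reseeds + 1L
    }
    new_centroids <- rowsum(x, assign, reorder = TRUE) / sizes
    wcss <- sum((x - new_centroids[assign, , drop = FALSE])^2)
    # plain Lloyd steps never increase the objective; a reseed may bump it
    # for one iteration, so the assertion is suspended in that case
    if (length(wcss_trace) && n_reseeds == 0L &&
        wcss > wcss_trace[length(wcss_trace)] * (1 + 1e-9) + 1e-12) {
      stop("internal error: WCSS increased across a Lloyd iteration")
    }
    wcss_trace <- c(wcss_trace, wcss)
    shift <- sqrt(max(rowSums((new_centroids - centroids)^2)))
    centroids <- new_centroids
    if (shift < tol || iter >= max_iter) break
  }
  list(cluster = assign, centroids = centroids, wcss = wcss_trace[iter],
       n_iterations = iter, wcss_trace = wcss_trace)
}

#' @export
print.cb_kmeans <- function(x, ...) {
  cat("k-means fit: k =", nrow(x$centroids), ", WCSS =",
      format(x$wcss, digits = 6), "after", x$n_iterations, "iterations\n")
  invisible(x)
}

#' Cluster features by their mutual-information profiles
#'
#' Partitions the retained features into `K` groups by running k-means on
#' the rows of the pairwise MI matrix: each feature is represented by its
#' MI profile against all retained features, so mutual information is the
#' sole geometry of the clustering. Cluster ids are arbitrary up to
#' relabeling; partitions should be compared as set partitions.
#'
#' @param mi An `mi_matrix` object from [pairwise_mi()].
#' @param K Number of clusters; default `max(2, round(sqrt(d)))` with `d`
#'   the retained-feature count.
#' @param n_restarts,max_iter,tol,seed Passed to [cb_kmeans()].
#' @return Object of class `cluster_assignment`: list with `cluster`
#'   (integer cluster id per retained feature, named by original 1-based
#'   feature index), `feature_index` (original indices), `K`, and `model`
#'   (the `cb_kmeans` fit).
#' @export
cluster_features <- function(mi, K = NULL, n_restarts = 10L,
                             max_iter = 300L, tol = 1e-6, seed = NULL) {
  stopifnot(inherits(mi, "mi_matrix"))
  d <- nrow(mi$mi)
  if (is.null(K)) K <- max(2L, as.integer(round(sqrt(d))))
  if (K < 1L) stop("K must be at least 1")
  if (K > d) stop("K (", K, ") exceeds retained feature count (", d, ")")
  fit <- cb_kmeans(mi$mi, K, n_restarts = n_restarts, max_iter = max_iter,
                   tol = tol, seed = seed)
  structure(
    list(cluster = stats::setNames(fit$cluster, mi$retained),
         feature_index = mi$retained, K = as.integer(K), model = fit),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- tabulate(x$cluster, nbins = x$K)
  cat("feature clustering: K =", x$K, "over", length(x$cluster),
      "retained features\n")
  cat("  cluster sizes: min", min(sizes), "/ median", median(sizes),
      "/ max", max(sizes), "\n")
  invisible(x)
}

#' Export a cluster assignment as a data frame
#'
#' @param assignment A `cluster_assignment` object.
#' @return Data frame with columns `feature_index`, `tripeptide`,
#'   `cluster_id`.
#' @export
cluster_table <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  data.frame(
    feature_index = assignment$feature_index,
    tripeptide = tripeptide_names()[assignment$feature_index],
    cluster_id = unname(assignment$cluster)
  )
}
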