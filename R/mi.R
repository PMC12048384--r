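# Mutual-information analysis of the feature matrix.
#
# TPC frequencies are continuous, so features are first discretized with
# equal-frequency binning; entropies and mutual information are then
# plug-in (empirical count) estimates in bits. The pairwise MI matrix,
# whose diagonal holds the per-feature entropies, is the geometry on which
# features are clustered.

#' Equal-frequency discretization
#'
#' Assigns each value to one of `n_bins` codes so that bin occupancies are
#' as equal as the tie structure allows. Ties are handled
#' deterministically: tied values share the lower bin (minimum-rank rule),
#' so a constant vector maps to a single code.
#'
#' @param values Finite numeric vector.
#' @param n_bins Number of bins (at least 2). If `n_bins` exceeds the
#'   number of samples it is clamped to it with a warning.
#' @return Integer vector of 0-based bin codes in `[0, n_bins - 1]`.
#' @export
discretize <- function(values, n_bins = 5L) {
  stopifnot(is.numeric(values))
  if (any(!is.finite(values))) stop("values must be finite")
  if (n_bins < 2L) stop("n_bins must be at least 2")
  n <- length(values)
  if (n_bins > n) {
    warning("n_bins (", n_bins, ") exceeds sample count (", n,
            "); clamping to ", n)
    n_bins <- n
  }
  r <- rank(values, ties.method = "min")
  as.integer(floor((r - 1) * n_bins / n))
}

#' Shannon entropy of a discrete distribution
#'
#' `H = -sum p log2 p` with the convention `0 * log 0 = 0`.
#'
#' @param p Probability vector (non-negative, sums to one within 1e-9).
#' @return Entropy in bits (non-negative scalar).
#' @export
entropy <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < -1e-12)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Empirical mutual information between two code vectors
#'
#' Plug-in estimate in bits from the empirical joint distribution of two
#' discrete variables. Three algebraically equivalent routes are
#' implemented and cross-checkable: the direct double sum over joint
#' cells, the entropy identity `H(X) + H(Y) - H(X, Y)`, and the expected
#' pointwise-mutual-information form (a per-sample average).
#'
#' @param x,y Equal-length vectors of discrete codes (any atomic type).
#' @param method `"joint"` (default), `"entropy"` or `"pmi"`.
#' @return Mutual information in bits (non-negative up to floating-point
#'   error).
#' @export
mutual_information <- function(x, y, method = c("joint", "entropy", "pmi")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n == 0L) stop("empty input")
  xf <- as.integer(factor(x))
  yf <- as.integer(factor(y))
  kx <- max(xf)
  ky <- max(yf)
  joint <- matrix(tabulate((yf - 1L) * kx + xf, nbins = kx * ky),
                  nrow = kx, ncol = ky) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  switch(method,
    joint = {
      cells <- which(joint > 0, arr.ind = TRUE)
      pj <- joint[cells]
      sum(pj * log2(pj / (px[cells[, 1]] * py[cells[, 2]])))
    },
    entropy = entropy(px) + entropy(py) - entropy(as.vector(joint)),
    pmi = {
      pmi <- log2(joint[cbind(xf, yf)] / (px[xf] * py[yf]))
      mean(pmi)
    }
  )
}

#' Pairwise mutual-information matrix over features
#'
#' Discretizes every feature column with equal-frequency binning and
#' computes the symmetric matrix of plug-in mutual information (in bits)
#' between all retained feature pairs. Diagonal entries hold the
#' per-feature entropies. Columns that are zero in every sample are
#' screened out first: they have zero entropy, carry zero MI with
#' everything, and would only inflate the quadratic pair computation. The
#' mapping back to original 1-based feature indices is preserved in
#' `retained`.
#'
#' @param x Numeric feature matrix (samples in rows) or `tpc_features`
#'   object.
#' @param n_bins Bins for [discretize()] (default 5).
#' @return Object of class `mi_matrix`: list with `mi` (symmetric numeric
#'   matrix over retained features, entropies on the diagonal), `retained`
#'   (original column indices), `n_bins`, and `unit = "bits"`.
#' @export
pairwise_mi <- function(x, n_bins = 5L) {
  if (inherits(x, "tpc_features")) x <- x$x
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) stop("pairwise MI needs at least 2 samples")
  retained <- which(colSums(abs(x)) > 0)
  if (length(retained) == 0L) stop("no non-zero feature columns retained")
  codes <- vapply(retained, function(j) discretize(x[, j], n_bins),
                  integer(nrow(x)))
  nb <- min(n_bins, nrow(x))
  mi <- mi_matrix_codes(codes, as.integer(nb))
  dimnames(mi) <- list(colnames(x)[retained], colnames(x)[retained])
  structure(
    list(mi = mi, retained = retained, n_bins = as.integer(nb),
         unit = "bits"),
    class = "mi_matrix"
  )
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat("pairwise MI matrix over", length(x$retained), "retained features (",
      x$n_bins, "bins,", x$unit, ")\n")
  invisible(x)
}

#' Mutual information of each feature with the class label
#'
#' Plug-in MI (bits) between each discretized feature column and the
#' class label. Used for reporting, for ranking selected features, and for
#' the optional relevance pre-filter.
#'
#' @param x Numeric feature matrix or `tpc_features` object.
#' @param labels Class labels (factor or character), one per row.
#' @param n_bins Bins for [discretize()].
#' @return Numeric vector of length `ncol(x)` of relevance values in bits
#'   (features that are all-zero get relevance 0).
#' @export
relevance_to_label <- function(x, labels, n_bins = 5L) {
  if (inherits(x, "tpc_features")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$x
  }
  stopifnot(is.matrix(x))
  labels <- as.factor(labels)
  if (length(labels) != nrow(x)) stop("labels must match rows of x")
  if (nlevels(labels) < 2L) {
    warning("single class: all relevance values are zero")
    return(stats::setNames(numeric(ncol(x)), colnames(x)))
  }
  retained <- which(colSums(abs(x)) > 0)
  out <- numeric(ncol(x))
  if (length(retained)) {
    codes <- vapply(retained, function(j) discretize(x[, j], n_bins),
                    integer(nrow(x)))
    nb <- min(n_bins, nrow(x))
    out[retained] <- mi_label_codes(codes, as.integer(labels) - 1L,
                                    as.integer(nb), nlevels(labels))
  }
  stats::setNames(out, colnames(x))
}
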