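# Pipeline orchestration: MI -> feature clustering -> per-cluster bGWO ->
# aggregation. Selection runs on a stratified training split only; the
# held-out rows are reserved for the evaluation stage.

#' Pipeline configuration
#'
#' Bundles every tunable of the selection pipeline. All stage seeds are
#' derived deterministically from `master_seed` (see [derive_seed()]), so
#' the whole pipeline is a pure function of (data, labels, config).
#'
#' @param n_bins Equal-frequency bins for discretization (default 5).
#' @param K Number of feature clusters; `NULL` (default) means
#'   `max(2, round(sqrt(d_retained)))`.
#' @param n_restarts,max_iter,tol k-means options (defaults 10, 300, 1e-6).
#' @param pop_size,n_iter bGWO population size and iteration count
#'   (defaults 10 and 30).
#' @param lambda Fitness weight on classification error vs sparsity,
#'   in (0, 1] (default 0.99).
#' @param cv_folds Inner cross-validation folds of the wrapper fitness
#'   (default 3).
#' @param inner_classifier Inner classifier of the fitness (default
#'   `"centroid"`, nearest class centroid).
#' @param prefilter_top_fraction Fraction in (0, 1] of retained features
#'   kept by the label-relevance pre-filter before clustering; 1 (default)
#'   disables the filter and relevance is reporting-only.
#' @param train_fraction Stratified train fraction for the selection split
#'   (default 0.7).
#' @param master_seed Integer master seed (default 1).
#' @return Object of class `cbbgwo_config` (a list of the above).
#' @export
pipeline_config <- function(n_bins = 5L, K = NULL, n_restarts = 10L,
                            max_iter = 300L, tol = 1e-6, pop_size = 10L,
                            n_iter = 30L, lambda = 0.99, cv_folds = 3L,
                            inner_classifier = "centroid",
                            prefilter_top_fraction = 1,
                            train_fraction = 0.7, master_seed = 1L) {
  if (prefilter_top_fraction <= 0 || prefilter_top_fraction > 1) {
    stop("prefilter_top_fraction must be in (0, 1]")
  }
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  structure(
    list(n_bins = as.integer(n_bins), K = K,
         n_restarts = as.integer(n_restarts),
         max_iter = as.integer(max_iter), tol = tol,
         pop_size = as.integer(pop_size), n_iter = as.integer(n_iter),
         lambda = lambda, cv_folds = as.integer(cv_folds),
         inner_classifier = inner_classifier,
         prefilter_top_fraction = prefilter_top_fraction,
         train_fraction = train_fraction,
         master_seed = as.integer(master_seed)),
    class = "cbbgwo_config"
  )
}

#' Run the cluster-guided bGWO feature-selection pipeline
#'
#' Executes the full selection procedure on a TPC feature matrix:
#' \enumerate{
#'   \item stratified train/held-out split (selection sees only the
#'     training rows);
#'   \item pairwise feature MI and feature-to-label relevance on the
#'     training rows, with an optional relevance pre-filter;
#'   \item k-means clustering of the retained features on their MI
#'     profiles;
#'   \item one bGWO run per cluster, each with its own derived seed,
#'     minimizing the wrapper fitness on that cluster's columns
#'     (single-feature clusters skip optimization and are kept iff the
#'     singleton's fitness beats the empty-subset baseline);
#'   \item aggregation of the per-cluster winners into the final sorted
#'     feature set.
#' }
#'
#' @param x Numeric feature matrix (samples x 8000) or `tpc_features`
#'   object.
#' @param labels Class labels (ignored when `x` is a labeled
#'   `tpc_features`).
#' @param config A [pipeline_config()] object.
#' @return Object of class `cbbgwo_selection`: list with
#'   `selected` (sorted 1-based feature indices), `selected_names`
#'   (tripeptides), `selected_fraction` (of the full 8000-dimensional
#'   space), `per_cluster` (cluster id -> solution summary),
#'   `clusters` (the `cluster_assignment`), `relevance` (bits, full
#'   length), `split` (train/test indices), `config` and `seeds`.
#' @export
cbbgwo_run <- function(x, labels = NULL, config = pipeline_config()) {
  if (inherits(x, "tpc_features")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$x
  }
  stopifnot(is.matrix(x), inherits(config, "cbbgwo_config"))
  labels <- as.factor(labels)
  if (length(labels) != nrow(x)) stop("labels must match rows of x")
  if (nlevels(labels) < 2L) stop("need at least 2 classes")

  seeds <- list(
    split = derive_seed(config$master_seed, "split"),
    kmeans = derive_seed(config$master_seed, "kmeans"),
    fitness = derive_seed(config$master_seed, "fitness")
  )
  split <- stratified_split(labels, config$train_fraction,
                            seed = seeds$split)
  x_tr <- x[split$train, , drop = FALSE]
  y_tr <- droplevels(labels[split$train])
  if (nlevels(y_tr) < 2L) stop("training split lost all but one class")

  # Step 1: MI structure and label relevance on the training rows
  mi <- pairwise_mi(x_tr, n_bins = config$n_bins)
  relevance <- relevance_to_label(x_tr, y_tr, n_bins = config$n_bins)

  if (config$prefilter_top_fraction < 1) {
    d_ret <- length(mi$retained)
    keep_n <- max(2L, as.integer(ceiling(config$prefilter_top_fraction * d_ret)))
    rel_ret <- relevance[mi$retained]
    ord <- order(-rel_ret, mi$retained)  # ties by ascending feature index
    keep <- sort(ord[seq_len(keep_n)])
    mi$mi <- mi$mi[keep, keep, drop = FALSE]
    mi$retained <- mi$retained[keep]
  }

  # Step 2: cluster features on their MI profiles
  clusters <- cluster_features(mi, K = config$K,
                               n_restarts = config$n_restarts,
                               max_iter = config$max_iter, tol = config$tol,
                               seed = seeds$kmeans)

  # Step 3: bGWO inside each cluster
  per_cluster <- vector("list", clusters$K)
  index_maps <- vector("list", clusters$K)
  for (cid in seq_len(clusters$K)) {
    cols <- clusters$feature_index[clusters$cluster == cid]
    index_maps[[cid]] <- cols
    xc <- x_tr[, cols, drop = FALSE]
    fit_fn <- make_fitness(xc, y_tr, lambda = config$lambda,
                           cv_folds = config$cv_folds,
                           classifier = config$inner_classifier,
                           seed = seeds$fitness)
    if (length(cols) == 1L) {
      f1 <- as.numeric(fit_fn(1L))
      keep <- f1 < config$lambda  # beat the empty-subset baseline
      per_cluster[[cid]] <- list(bits = as.integer(keep), fitness = f1,
                                 n_selected = as.integer(keep),
                                 singleton = TRUE)
    } else {
      sol <- bgwo_optimize(length(cols), fit_fn,
                           pop_size = config$pop_size,
                           n_iter = config$n_iter,
                           seed = derive_seed(config$master_seed, "bgwo", cid))
      per_cluster[[cid]] <- sol
    }
  }

  # Step 4: aggregate the per-cluster winners
  selected <- aggregate_selections(per_cluster, index_maps)

  structure(
    list(selected = selected,
         selected_names = tripeptide_names()[selected],
         selected_fraction = length(selected) / N_TRIPEPTIDES,
         per_cluster = per_cluster, index_maps = index_maps,
         clusters = clusters, relevance = relevance,
         retained = mi$retained, split = split,
         config = config, seeds = seeds),
    class = "cbbgwo_selection"
  )
}

#' Aggregate per-cluster selections into one sorted feature set
#'
#' Maps each cluster's selected bits back to original 1-based feature
#' indices and takes the union. The per-cluster index maps must form a
#' partition (pairwise disjoint); overlap is an error.
#'
#' @param per_cluster List of solutions, each with a `bits` element over
#'   the corresponding cluster's features.
#' @param index_maps List of integer vectors: original feature indices of
#'   each cluster's columns.
#' @return Sorted integer vector of selected original feature indices
#'   (empty, with a warning, when nothing was selected).
#' @export
aggregate_selections <- function(per_cluster, index_maps) {
  stopifnot(length(per_cluster) == length(index_maps))
  all_idx <- unlist(index_maps)
  if (anyDuplicated(all_idx)) {
    stop("index maps overlap: feature ", all_idx[duplicated(all_idx)][1],
         " appears in more than one cluster")
  }
  sel <- unlist(lapply(seq_along(per_cluster), function(cid) {
    bits <- per_cluster[[cid]]$bits
    index_maps[[cid]][bits != 0]
  }))
  if (length(sel) == 0L) {
    warning("no features selected in any cluster")
    return(integer(0))
  }
  sort(unique(as.integer(sel)))
}

#' Rank selected features by label relevance
#'
#' Orders the selected features by their mutual information with the
#' class label (descending, ties broken by ascending feature index) and
#' reports the top of the list with tripeptide names and cluster of
#' origin.
#'
#' @param result A `cbbgwo_selection` object.
#' @param top_n Number of rows to return (default 10; `Inf` for all).
#' @return Data frame with columns `rank`, `feature_index`, `tripeptide`,
#'   `relevance_bits`, `cluster_id`.
#' @export
rank_selected <- function(result, top_n = 10L) {
  stopifnot(inherits(result, "cbbgwo_selection"))
  sel <- result$selected
  if (length(sel) == 0L) stop("empty selection")
  rel <- result$relevance[sel]
  ord <- order(-rel, sel)
  sel <- sel[ord]
  cluster_of <- rep(NA_integer_, length(sel))
  for (cid in seq_along(result$index_maps)) {
    cluster_of[sel %in% result$index_maps[[cid]]] <- cid
  }
  n <- min(length(sel), top_n)
  data.frame(
    rank = seq_len(n),
    feature_index = sel[seq_len(n)],
    tripeptide = tripeptide_names()[sel[seq_len(n)]],
    relevance_bits = unname(rel[ord][seq_len(n)]),
    cluster_id = cluster_of[seq_len(n)]
  )
}

#' @export
print.cbbgwo_selection <- function(x, ...) {
  cat("CB-BGWO selection\n")
  cat("  retained features:", length(x$retained), "of", N_TRIPEPTIDES, "\n")
  cat("  clusters (K):     ", x$clusters$K, "\n")
  cat("  selected features:", length(x$selected),
      sprintf("(%.1f%% of the full space)", 100 * x$selected_fraction), "\n")
  invisible(x)
}

#' Export a selection result
#'
#' Writes `selected_features.tsv` (index, tripeptide, cluster, relevance)
#' and `selection_report.json` (configuration, seeds, per-cluster
#' summaries) into a directory.
#'
#' @param result A `cbbgwo_selection` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_selection <- function(result, dir) {
  stopifnot(inherits(result, "cbbgwo_selection"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- rank_selected(result, top_n = Inf)
  write.table(tab, file.path(dir, "selected_features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report <- list(
    n_selected = length(result$selected),
    selected_fraction = result$selected_fraction,
    K = result$clusters$K,
    n_retained = length(result$retained),
    config = unclass(result$config),
    seeds = result$seeds,
    per_cluster = lapply(seq_along(result$per_cluster), function(cid) {
      s <- result$per_cluster[[cid]]
      list(cluster_id = cid, n_features = length(result$index_maps[[cid]]),
           n_selected = s$n_selected, fitness = s$fitness)
    })
  )
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(dir, "selection_report.json"))
  for (cid in seq_along(result$per_cluster)) {
    s <- result$per_cluster[[cid]]
    if (!is.null(s$trace)) {
      utils::write.csv(s$trace,
                       file.path(dir, sprintf("trace_cluster_%03d.csv", cid)),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
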