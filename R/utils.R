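# Stage-seed derivation -------------------------------------------------
#
# Every stochastic stage of the pipeline draws its own seed from the master
# seed through this deterministic scheme, so a single stage can be re-run in
# isolation and reproduce exactly what the full pipeline did. Cluster-level
# optimizer runs use stage "bgwo" with the cluster id as index.
.stage_codes <- c(
  motifs    = 1L,
  sequences = 2L,
  split     = 3L,
  kmeans    = 4L,
  fitness   = 5L,
  eval      = 6L,
  null      = 7L,
  bgwo      = 100L
)

#' Derive a stage seed from a master seed
#'
#' Deterministic arithmetic scheme mapping `(master_seed, stage, index)` to
#' an integer seed below 2^31, used by every stochastic stage of the
#' pipeline so that stages are individually reproducible.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name, one of `"motifs"`, `"sequences"`, `"split"`,
#'   `"kmeans"`, `"fitness"`, `"eval"`, `"null"`, `"bgwo"`.
#' @param index Non-negative integer sub-index (e.g. cluster id for the
#'   per-cluster optimizer stage).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stage, index = 0L) {
  stage <- match.arg(stage, names(.stage_codes))
  code <- as.double(.stage_codes[[stage]]) + as.double(index)
  as.integer((as.double(master_seed) %% 2147483647 * 7919 + code * 104729) %%
               2147483647)
}

# Stratified assignment of samples to folds/splits. Returns an integer
# vector of group ids 1..k with class proportions preserved per group.
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified train/test split; returns list(train, test) of row indices.
stratified_split <- function(labels, train_fraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.factor(labels)
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(train_fraction * length(idx)))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
    take <- idx[sample.int(length(idx))][seq_len(n_tr)]
    train <- c(train, take)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
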