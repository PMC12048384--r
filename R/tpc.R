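# Tripeptide composition (TPC) encoding.
#
# A protein of length L has L - 2 overlapping 3-residue windows; the TPC
# vector holds the frequency alpha_i = D_i / (L - 2) of every one of the
# 20^3 = 8000 possible tripeptides, where D_i is the window count of
# tripeptide i. Feature indices are 1-based and lexicographic over
# AA_ALPHABET, so "AAA" -> 1 and "YYY" -> 8000.

N_TRIPEPTIDES <- 8000L

#' All 8000 tripeptide names in index order
#'
#' @return Character vector of length 8000; element `i` is the tripeptide
#'   whose feature index is `i` (lexicographic over [AA_ALPHABET]).
#' @export
tripeptide_names <- function() {
  paste0(rep(AA_ALPHABET, each = 400L),
         rep(rep(AA_ALPHABET, each = 20L), times = 20L),
         rep(AA_ALPHABET, times = 400L))
}

#' Map tripeptides to 1-based feature indices
#'
#' Deterministic bijection between the 8000 canonical tripeptides and the
#' integers 1..8000: `index = 400 r1 + 20 r2 + r3 + 1` with `r` the 0-based
#' residue ranks in [AA_ALPHABET].
#'
#' @param tripeptide Character vector of 3-residue strings.
#' @param alphabet_policy `"strict"` errors on non-canonical residues;
#'   `"permissive"` returns `NA` ("unindexed") for them.
#' @return Integer vector of feature indices in `[1, 8000]` (or `NA` under
#'   the permissive policy).
#' @export
tripeptide_index <- function(tripeptide,
                             alphabet_policy = c("strict", "permissive")) {
  alphabet_policy <- match.arg(alphabet_policy)
  stopifnot(is.character(tripeptide))
  if (any(nchar(tripeptide) != 3L)) {
    stop("tripeptides must be exactly 3 residues long")
  }
  r1 <- match(substr(tripeptide, 1L, 1L), AA_ALPHABET) - 1L
  r2 <- match(substr(tripeptide, 2L, 2L), AA_ALPHABET) - 1L
  r3 <- match(substr(tripeptide, 3L, 3L), AA_ALPHABET) - 1L
  idx <- 400L * r1 + 20L * r2 + r3 + 1L
  if (anyNA(idx) && alphabet_policy == "strict") {
    bad <- tripeptide[is.na(idx)][1]
    stop("non-canonical residue in tripeptide '", bad, "'")
  }
  idx
}

#' Encode one protein sequence as a TPC frequency vector
#'
#' Counts the `L - 2` overlapping tripeptide windows of the sequence and
#' divides by `L - 2`. Under the strict alphabet policy (the default after
#' strict preprocessing) every window is canonical and the entries sum to
#' one. Under the permissive policy, windows containing a non-canonical
#' residue contribute to no count but the denominator remains `L - 2`, so
#' the entries may sum to less than one; this keeps the frequency
#' definition literal at the cost of normalization.
#'
#' @param sequence A single amino-acid string of length at least 3.
#' @param alphabet_policy `"strict"` (error on non-canonical residues) or
#'   `"permissive"` (skip affected windows).
#' @return Numeric vector of length 8000 with attributes `seq_length`
#'   (residues) and `n_windows`.
#' @export
encode_sequence <- function(sequence,
                            alphabet_policy = c("strict", "permissive")) {
  alphabet_policy <- match.arg(alphabet_policy)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 3L) stop("no tripeptide window: sequence length ", L, " < 3")
  codes <- match(strsplit(sequence, "", fixed = TRUE)[[1]], AA_ALPHABET) - 1L
  if (anyNA(codes) && alphabet_policy == "strict") {
    stop("non-canonical residue in sequence (position ",
         which(is.na(codes))[1], "); use alphabet_policy = 'permissive' ",
         "or strict preprocessing")
  }
  n_win <- L - 2L
  idx <- 400L * codes[seq_len(n_win)] +
    20L * codes[seq_len(n_win) + 1L] +
    codes[seq_len(n_win) + 2L] + 1L
  counts <- tabulate(idx[!is.na(idx)], nbins = N_TRIPEPTIDES)
  out <- counts / n_win
  attr(out, "seq_length") <- L
  attr(out, "n_windows") <- n_win
  out
}

#' Encode a set of protein records as a feature matrix
#'
#' @param records Data frame of preprocessed records (`id`, `sequence`,
#'   optionally `label`).
#' @param alphabet_policy Passed to [encode_sequence()].
#' @return A list of class `tpc_features` with elements `x` (numeric
#'   matrix, one row per record, 8000 columns named by tripeptide;
#'   rownames are record ids) and `labels` (factor, or `NULL` when the
#'   records are unlabeled).
#' @export
encode_dataset <- function(records,
                           alphabet_policy = c("strict", "permissive")) {
  alphabet_policy <- match.arg(alphabet_policy)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("cannot encode an empty record set")
  rows <- lapply(seq_len(nrow(records)), function(i) {
    tryCatch(
      encode_sequence(records$sequence[i], alphabet_policy),
      error = function(e) {
        stop("record '", records$id[i], "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
  })
  x <- do.call(rbind, rows)
  dimnames(x) <- list(records$id, tripeptide_names())
  labels <- if ("label" %in% names(records)) factor(records$label) else NULL
  structure(list(x = x, labels = labels), class = "tpc_features")
}

#' @export
print.tpc_features <- function(x, ...) {
  cat("TPC feature matrix:", nrow(x$x), "sequences x", ncol(x$x),
      "tripeptide features\n")
  if (!is.null(x$labels)) {
    cat("  classes:", paste(levels(x$labels), collapse = ", "), "\n")
  }
  cat("  non-zero columns:", sum(colSums(x$x) > 0), "\n")
  invisible(x)
}

#' Summary statistics of a feature matrix
#'
#' Population statistics (variance with denominator `n`) over all matrix
#' entries, and optionally per feature column.
#'
#' @param x A `tpc_features` object or numeric matrix.
#' @param per_feature If `TRUE`, also return a per-column summary matrix.
#' @return A list of class `feature_summary` with scalar `mean`, `median`,
#'   `sd`, `variance`, and optionally `per_feature`.
#' @export
summarize_features <- function(x, per_feature = FALSE) {
  if (inherits(x, "tpc_features")) x <- x$x
  stopifnot(is.matrix(x))
  if (length(x) == 0L) stop("cannot summarize an empty matrix")
  m <- mean(x)
  v <- mean((x - m)^2)
  out <- list(mean = m, median = median(x), sd = sqrt(v), variance = v)
  if (per_feature) {
    mf <- colMeans(x)
    vf <- colMeans(x^2) - mf^2
    out$per_feature <- cbind(mean = mf, variance = vf)
  }
  structure(out, class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, ...) {
  cat(sprintf("feature summary: mean %.6g, median %.6g, sd %.6g, variance %.6g\n",
              x$mean, x$median, x$sd, x$variance))
  invisible(x)
}

#' Export a feature matrix to TSV
#'
#' Writes one row per sequence with `id`, `label` and the 8000 tripeptide
#' columns.
#'
#' @param features A `tpc_features` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(features, path) {
  stopifnot(inherits(features, "tpc_features"))
  df <- data.frame(id = rownames(features$x),
                   label = if (is.null(features$labels)) NA_character_
                           else as.character(features$labels),
                   features$x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
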