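# Planted-motif synthetic protein generator.
#
# Emulates the statistical structure the pipeline assumes: multi-class
# sets of amino-acid sequences over the canonical 20-letter alphabet in
# which each class is enriched for a small, class-specific set of
# tripeptide motifs on top of a uniform residue background. Because each
# motif is exactly one tripeptide, the planted truth maps one-to-one onto
# TPC feature indices, giving exact ground truth for recovery benchmarks.

#' Generate labeled synthetic protein sequences with planted motifs
#'
#' For each sequence: the length is drawn uniformly from `length_range`,
#' residues are filled i.i.d. from the `background` distribution, and a
#' Poisson(`insertion_rate`) number of motif copies — each drawn uniformly
#' from the sequence's class motif set — are written at uniformly chosen
#' non-overlapping positions. Motif sets are disjoint across classes.
#' Every generated sequence satisfies the default preprocessing filters
#' (length at least 20, canonical alphabet); identical seeds give
#' identical output.
#'
#' @param n_classes Number of classes (default 4).
#' @param n_per_class Sequences per class (default 60).
#' @param length_range Length range in residues, minimum at least 20
#'   (default `c(80, 150)`).
#' @param motifs_per_class Planted tripeptide motifs per class (default 3).
#' @param insertion_rate Expected motif insertions per sequence (Poisson
#'   mean, default 8; 0 gives null data with no class signal).
#' @param background Residue probabilities over [AA_ALPHABET] (default
#'   uniform).
#' @param class_names Optional class names (default `class_1`, ...).
#' @param seed Integer master seed (default 1).
#' @return Object of class `synthetic_proteins`: list with `records`
#'   (data.frame `id`, `sequence`, `label`), `truth` (class name ->
#'   sorted planted 1-based feature indices), `motifs` (class ->
#'   tripeptide strings) and the generator settings.
#' @export
generate_synthetic <- function(n_classes = 4L, n_per_class = 60L,
                               length_range = c(80L, 150L),
                               motifs_per_class = 3L, insertion_rate = 8,
                               background = NULL, class_names = NULL,
                               seed = 1L) {
  if (n_classes < 1L || n_per_class < 1L) stop("need at least one sequence")
  if (length_range[1] < 20L) stop("minimum length must be at least 20")
  if (length_range[2] < length_range[1]) stop("invalid length range")
  if (insertion_rate < 0) stop("insertion_rate must be non-negative")
  if (is.null(background)) background <- rep(1 / 20, 20L)
  if (length(background) != 20L || any(background < 0)) {
    stop("background must be 20 non-negative probabilities")
  }
  background <- background / sum(background)
  if (is.null(class_names)) {
    class_names <- paste0("class_", seq_len(n_classes))
  }
  stopifnot(length(class_names) == n_classes)

  # disjoint class motif sets, drawn from the 8000 tripeptides
  set.seed(derive_seed(seed, "motifs"))
  motif_idx <- sample.int(N_TRIPEPTIDES, n_classes * motifs_per_class)
  trinames <- tripeptide_names()
  motifs <- split(trinames[motif_idx],
                  rep(class_names, each = motifs_per_class))
  truth <- lapply(split(motif_idx, rep(class_names, each = motifs_per_class)),
                  sort)

  set.seed(derive_seed(seed, "sequences"))
  ids <- character(n_classes * n_per_class)
  seqs <- character(n_classes * n_per_class)
  labs <- character(n_classes * n_per_class)
  row <- 0L
  for (ci in seq_len(n_classes)) {
    cl <- class_names[ci]
    for (si in seq_len(n_per_class)) {
      L <- sample(seq.int(length_range[1], length_range[2]), 1L)
      residues <- sample(AA_ALPHABET, L, replace = TRUE, prob = background)
      n_ins <- rpois(1L, insertion_rate)
      if (n_ins > 0L) {
        residues <- plant_motifs(residues, motifs[[cl]], n_ins)
      }
      row <- row + 1L
      ids[row] <- sprintf("%s_seq%04d", cl, si)
      seqs[row] <- paste(residues, collapse = "")
      labs[row] <- cl
    }
  }

  structure(
    list(records = data.frame(id = ids, sequence = seqs, label = labs,
                              stringsAsFactors = FALSE),
         truth = truth[class_names], motifs = motifs[class_names],
         n_classes = n_classes, n_per_class = n_per_class,
         length_range = length_range, motifs_per_class = motifs_per_class,
         insertion_rate = insertion_rate, seed = seed),
    class = "synthetic_proteins"
  )
}

# Overwrite n_ins motif copies at uniformly chosen non-overlapping start
# positions. Placing a motif at start p blocks starts p-2 .. p+2.
plant_motifs <- function(residues, class_motifs, n_ins) {
  L <- length(residues)
  available <- rep(TRUE, L - 2L)
  for (k in seq_len(n_ins)) {
    open <- which(available)
    if (length(open) == 0L) {
      stop("motif demand exceeds sequence capacity (length ", L,
           ", requested ", n_ins, " insertions)")
    }
    p <- open[sample.int(length(open), 1L)]
    motif <- class_motifs[sample.int(length(class_motifs), 1L)]
    residues[p:(p + 2L)] <- strsplit(motif, "")[[1]]
    blocked <- max(1L, p - 2L):min(L - 2L, p + 2L)
    available[blocked] <- FALSE
  }
  residues
}

#' @export
print.synthetic_proteins <- function(x, ...) {
  cat("synthetic protein set:", nrow(x$records), "sequences,",
      x$n_classes, "classes,", x$motifs_per_class,
      "planted motifs/class, insertion rate", x$insertion_rate, "\n")
  invisible(x)
}

#' Write a synthetic set as FASTA plus label table
#'
#' @param synth A `synthetic_proteins` object.
#' @param fasta_path,labels_path,truth_path Output paths (the planted
#'   truth JSON is optional).
#' @return Invisibly, `fasta_path`.
#' @export
write_synthetic <- function(synth, fasta_path, labels_path,
                            truth_path = NULL) {
  stopifnot(inherits(synth, "synthetic_proteins"))
  write_fasta(synth$records, fasta_path)
  write.table(synth$records[, c("id", "label")], labels_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth_path)) {
    writeLines(jsonlite::toJSON(synth$truth, auto_unbox = FALSE,
                                digits = NA, pretty = TRUE), truth_path)
  }
  invisible(fasta_path)
}

#' Recovery of planted features by a selection
#'
#' @param selected Integer vector of selected 1-based feature indices.
#' @param truth Planted truth: either a `synthetic_proteins` object or its
#'   `truth` list (class -> planted feature indices).
#' @return Named numeric vector `c(recall, precision)`:
#'   `recall = |selected n planted| / |planted|`,
#'   `precision = |selected n planted| / |selected|` (0, with attribute
#'   `empty_selection`, when nothing was selected).
#' @export
recovery_metrics <- function(selected, truth) {
  if (inherits(truth, "synthetic_proteins")) truth <- truth$truth
  planted <- sort(unique(unlist(truth)))
  if (length(planted) == 0L) stop("empty planted truth")
  selected <- unique(as.integer(selected))
  hit <- length(intersect(selected, planted))
  out <- c(recall = hit / length(planted),
           precision = if (length(selected) == 0L) 0
                       else hit / length(selected))
  if (length(selected) == 0L) attr(out, "empty_selection") <- TRUE
  out
}
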