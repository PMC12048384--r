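# FASTA input/output and dataset preprocessing.
#
# Records travel through the package as a plain data.frame with columns
# `id`, `sequence` and (after labeling) `label` — one row per protein.

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a data frame of protein records. Wrapped
#' sequence lines are concatenated, surrounding whitespace is stripped and
#' residues are upper-cased. The record id is the first whitespace-delimited
#' token of the header line; input order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with character columns `id` and `sequence`.
#' @seealso [write_fasta()], [preprocess()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop("failed to parse FASTA file '", path, "': ", conditionMessage(e))
    }
  )
  headers <- names(set)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for FASTA record '", headers[which(empty)[1]], "'")
  }
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[[`, character(1), 1L)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read an id-to-class label table
#'
#' Reads a tab-separated table with header columns `id` and `label`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with character columns `id` and `label`.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("label table not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("id", "label") %in% names(tab))) {
    stop("label table must have header columns 'id' and 'label'")
  }
  tab[, c("id", "label")]
}

#' Attach class labels to protein records
#'
#' Joins a label table onto a set of records. Records without an entry in
#' the table are dropped and reported in the `"unlabeled"` attribute of the
#' result. Each id must be labeled with exactly one class.
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param labels Data frame with columns `id` and `label`; ids must be
#'   unique.
#' @return The labeled records (columns `id`, `sequence`, `label`), in
#'   input order, with attribute `"unlabeled"` holding the ids of dropped
#'   records.
#' @export
attach_labels <- function(records, labels) {
  stopifnot(is.data.frame(records), is.data.frame(labels))
  if (anyDuplicated(labels$id)) {
    dup <- labels$id[duplicated(labels$id)][1]
    stop("duplicate id in label table: '", dup, "'")
  }
  hit <- match(records$id, labels$id)
  if (all(is.na(hit))) {
    stop("no record ids match the label table")
  }
  unlabeled <- records$id[is.na(hit)]
  if (length(unlabeled)) {
    message(length(unlabeled), " record(s) without a label were dropped")
  }
  out <- records[!is.na(hit), , drop = FALSE]
  out$label <- labels$label[hit[!is.na(hit)]]
  rownames(out) <- NULL
  attr(out, "unlabeled") <- unlabeled
  out
}

#' Preprocess labeled protein records
#'
#' Applies the dataset-cleaning filters, in this fixed order:
#' \enumerate{
#'   \item records with a missing or empty sequence are removed;
#'   \item records shorter than `min_length` residues are removed
#'     (a sequence of exactly `min_length` residues is retained);
#'   \item exact duplicate sequences are removed, keeping the first
#'     occurrence in input order (labels are ignored when comparing);
#'   \item under the `"strict"` alphabet policy, records containing any
#'     residue outside the canonical 20-letter alphabet are removed;
#'     `"permissive"` keeps them and defers handling to the encoder.
#' }
#' The filter order is deterministic, and re-running `preprocess()` on its
#' own output is the identity.
#'
#' @param records Data frame of labeled records (`id`, `sequence`,
#'   optionally `label`).
#' @param min_length Minimum retained sequence length in residues
#'   (default 20; must be at least 3 so at least one tripeptide window
#'   exists).
#' @param alphabet_policy `"strict"` (default) or `"permissive"`.
#' @return A list with elements `records` (the retained rows, input order)
#'   and `report`, an object of class `preprocess_report` with counts
#'   `n_input`, `n_removed_short`, `n_removed_duplicate`,
#'   `n_removed_invalid`, `n_kept` and a data.frame `removed_ids`
#'   (`id`, `reason`).
#' @export
preprocess <- function(records, min_length = 20L,
                       alphabet_policy = c("strict", "permissive")) {
  alphabet_policy <- match.arg(alphabet_policy)
  stopifnot(is.data.frame(records))
  if (min_length < 3L) stop("min_length must be at least 3")
  n_input <- nrow(records)
  removed <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(df, which, reason) {
    if (any(which)) {
      removed <<- rbind(removed, data.frame(id = df$id[which], reason = reason,
                                            stringsAsFactors = FALSE))
    }
    df[!which, , drop = FALSE]
  }

  cur <- records
  cur$sequence <- toupper(ifelse(is.na(cur$sequence), "", cur$sequence))
  cur <- drop(cur, !nzchar(cur$sequence), "missing")
  cur <- drop(cur, nchar(cur$sequence) < min_length, "short")
  cur <- drop(cur, duplicated(cur$sequence), "duplicate")
  if (alphabet_policy == "strict") {
    bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                 cur$sequence)
    cur <- drop(cur, bad, "invalid")
  }
  if (nrow(cur) == 0L) stop("empty dataset after preprocessing")
  if (anyDuplicated(cur$id)) {
    stop("record ids are not unique after preprocessing: '",
         cur$id[duplicated(cur$id)][1], "'")
  }
  rownames(cur) <- NULL

  tally <- function(reason) sum(removed$reason == reason)
  report <- structure(
    list(
      n_input = n_input,
      n_removed_missing = tally("missing"),
      n_removed_short = tally("short"),
      n_removed_duplicate = tally("duplicate"),
      n_removed_invalid = tally("invalid"),
      n_kept = nrow(cur),
      removed_ids = removed,
      min_length = min_length,
      alphabet_policy = alphabet_policy
    ),
    class = "preprocess_report"
  )
  list(records = cur, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocessing report\n")
  cat("  input records:    ", x$n_input, "\n")
  cat("  removed (missing):", x$n_removed_missing, "\n")
  cat("  removed (short):  ", x$n_removed_short,
      sprintf(" (min_length = %d)", x$min_length), "\n")
  cat("  removed (dup):    ", x$n_removed_duplicate, "\n")
  cat("  removed (invalid):", x$n_removed_invalid,
      sprintf(" (policy = %s)", x$alphabet_policy), "\n")
  cat("  kept:             ", x$n_kept, "\n")
  invisible(x)
}

#' Serialize a preprocessing report to JSON
#'
#' @param report A `preprocess_report` object.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "preprocess_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
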