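# Fixtures built in code: random protein records and tiny labeled
# datasets used across the unit tests.

random_records <- function(n, len_range = c(20L, 60L), seed = NULL,
                           prefix = "prot") {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(seq.int(len_range[1], len_range[2]), n, replace = TRUE)
  data.frame(
    id = sprintf("%s_%03d", prefix, seq_len(n)),
    sequence = vapply(lens, function(L) {
      paste(sample(cbbgwo::AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

write_fasta_text <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# brute-force tripeptide window counter used as the encoding oracle
oracle_tpc <- function(sequence) {
  L <- nchar(sequence)
  counts <- stats::setNames(numeric(8000), cbbgwo::tripeptide_names())
  for (i in seq_len(L - 2)) {
    w <- substr(sequence, i, i + 2)
    counts[w] <- counts[w] + 1
  }
  counts / (L - 2)
}

# exhaustive-search WCSS oracle over all assignments of <= 8 points
oracle_best_wcss <- function(x, k) {
  n <- nrow(x)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < k) next
    w <- 0
    for (g in unique(a)) {
      pts <- x[a == g, , drop = FALSE]
      mu <- colMeans(pts)
      w <- w + sum(sweep(pts, 2, mu)^2)
    }
    best <- min(best, w)
  }
  best
}

# small separable 2-class dataset for classifier sanity checks
separable_toy <- function(n_per_class = 15L, seed = 42L) {
  set.seed(seed)
  x <- rbind(
    matrix(stats::rnorm(n_per_class * 4, mean = 0), ncol = 4),
    matrix(stats::rnorm(n_per_class * 4, mean = 4), ncol = 4)
  )
  y <- factor(rep(c("a", "b"), each = n_per_class))
  list(x = x, y = y)
}
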