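test_that("equal-frequency discretization follows the min-rank tie rule", {
  expect_equal(discretize(c(0, 0, 0, 0), n_bins = 2), rep(0L, 4))

  set.seed(1)
  x <- sample(seq(0.1, 1, by = 0.1))  # 10 distinct values
  codes <- discretize(x, n_bins = 2)
  expect_equal(sort(tabulate(codes + 1L, 2)), c(5L, 5L))
  expect_equal(codes[order(x)], rep(0:1, each = 5))

  expect_warning(codes2 <- discretize(c(1, 2, 3), n_bins = 5), "clamping")
  expect_equal(codes2, 0:2)
  expect_error(discretize(c(1, NA), 2), "finite")
  expect_error(discretize(1:4, 1), "at least 2")
})

test_that("discretization matches a sort-and-split oracle on random input", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 50L
    x <- round(runif(n), 2)  # forces some ties
    nb <- sample(2:6, 1)
    codes <- discretize(x, nb)
    # oracle: code of the smallest untied rank
    oracle <- floor((rank(x, ties.method = "min") - 1) * nb / n)
    expect_equal(codes, as.integer(oracle))
    # monotone in the values
    expect_true(all(diff(codes[order(x)]) >= 0))
    # occupancy balanced up to tie multiplicity
    tied <- max(table(x))
    expect_lte(diff(range(tabulate(codes + 1L, nb))), tied + n %% nb)
  }
})

test_that("entropy reproduces closed-form values", {
  expect_equal(entropy(c(0.5, 0.5)), 1)
  expect_equal(entropy(1), 0)
  expect_equal(entropy(c(1, 0, 0)), 0)
  expect_equal(entropy(rep(1 / 8, 8)), 3)
  expect_error(entropy(c(0.3, 0.3)), "sum to 1")
  expect_error(entropy(c(1.2, -0.2)), "non-negative")
})

test_that("mutual information matches identity and independence cases", {
  x <- rep(c(0L, 1L), each = 10)
  expect_equal(mutual_information(x, x), 1)  # I(X;X) = H(X) = 1 bit

  # exact product-form joint counts -> independence -> I = 0
  xi <- rep(c(0L, 1L), each = 6)
  yi <- rep(c(0L, 1L, 2L), times = 4)
  expect_equal(mutual_information(xi, yi), 0, tolerance = 1e-12)

  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("mutual information matches a direct summation oracle on 3x3 tables", {
  set.seed(7)
  for (rep in 1:10) {
    counts <- matrix(rpois(9, 4) + 1L, 3, 3)
    x <- rep(rep(0:2, 3), as.vector(counts))
    y <- rep(rep(0:2, each = 3), as.vector(counts))
    n <- sum(counts)
    p <- counts / n
    px <- rowSums(p); py <- colSums(p)
    oracle <- 0
    for (a in 1:3) for (b in 1:3) {
      if (p[a, b] > 0) oracle <- oracle + p[a, b] * log2(p[a, b] / (px[a] * py[b]))
    }
    expect_equal(mutual_information(x, y), oracle, tolerance = 1e-12)
  }
})

test_that("the three MI computation routes agree and MI is symmetric", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    x <- sample.int(sample(2:5, 1), n, replace = TRUE)
    y <- sample.int(sample(2:5, 1), n, replace = TRUE)
    mj <- mutual_information(x, y, method = "joint")
    me <- mutual_information(x, y, method = "entropy")
    mp <- mutual_information(x, y, method = "pmi")
    expect_equal(mj, me, tolerance = 1e-10)
    expect_equal(mj, mp, tolerance = 1e-10)
    expect_equal(mj, mutual_information(y, x), tolerance = 1e-12)
    expect_gte(mj, -1e-12)
  }
})

test_that("merging bins never increases mutual information", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 60
    x <- sample.int(4, n, replace = TRUE)
    y <- sample.int(4, n, replace = TRUE)
    x_merged <- pmin(x, 3L)  # merge codes 3 and 4
    expect_lte(mutual_information(x_merged, y),
               mutual_information(x, y) + 1e-12)
  }
})

test_that("pairwise MI matrix is symmetric with entropies on the diagonal", {
  set.seed(29)
  x <- matrix(runif(30 * 6), nrow = 30)
  x[, 4] <- x[, 2]           # duplicated feature
  colnames(x) <- paste0("f", 1:6)
  m <- pairwise_mi(x, n_bins = 3)
  expect_equal(m$mi, t(m$mi))
  expect_true(all(m$mi >= 0))
  for (j in 1:6) {
    expect_equal(m$mi[j, j], entropy(tabulate(discretize(x[, j], 3) + 1L, 3) / 30),
                 tolerance = 1e-12)
  }
  # duplicate columns: off-diagonal MI equals the entropy and is row-maximal
  expect_equal(m$mi[2, 4], m$mi[2, 2], tolerance = 1e-12)
  expect_equal(unname(which.max(m$mi[2, -2])), 3L)  # column 4 after dropping col 2
})

test_that("pairwise MI matrix is permutation-equivariant and screens zeros", {
  set.seed(31)
  x <- matrix(runif(25 * 5), nrow = 25)
  x <- cbind(x, 0)  # an all-zero column to screen out
  colnames(x) <- paste0("f", 1:6)
  m <- pairwise_mi(x, n_bins = 4)
  expect_equal(unname(m$retained), 1:5)

  perm <- c(3L, 1L, 5L, 2L, 4L)
  mp <- pairwise_mi(x[, c(perm, 6L)], n_bins = 4)
  expect_equal(unname(mp$mi), unname(m$mi[perm, perm]), tolerance = 1e-12)

  # constant non-zero features carry zero entropy and zero MI
  xc <- matrix(0.5, nrow = 10, ncol = 3)
  xc[1, 1] <- 0.5  # still constant
  mc <- pairwise_mi(xc, n_bins = 3)
  expect_true(all(mc$mi == 0))

  expect_error(pairwise_mi(x[1, , drop = FALSE]), "2 samples")
})

test_that("label relevance identifies informative and constant features", {
  set.seed(37)
  labels <- factor(rep(c("a", "b"), each = 15))
  x <- cbind(
    ident = as.numeric(labels == "a"),      # identical to the label coding
    const = rep(0.3, 30),                   # constant, zero relevance
    noise = runif(30)
  )
  rel <- relevance_to_label(x, labels, n_bins = 2)
  expect_equal(unname(rel["ident"]), 1)     # H(label) = 1 bit
  expect_equal(unname(rel["const"]), 0)
  expect_lt(rel["noise"], rel["ident"])

  expect_warning(rel1 <- relevance_to_label(x, factor(rep("a", 30))),
                 "single class")
  expect_equal(unname(rel1), rep(0, 3))
})

test_that("planted-motif features rank above the background median relevance", {
  synth <- generate_synthetic(n_classes = 3, n_per_class = 15,
                              length_range = c(60, 80), motifs_per_class = 2,
                              insertion_rate = 5, seed = 19)
  feats <- encode_dataset(synth$records)
  rel <- relevance_to_label(feats$x, feats$labels)
  planted <- unlist(synth$truth)
  background <- setdiff(which(colSums(feats$x) > 0), planted)
  expect_true(all(rel[planted] > median(rel[background])))
})
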