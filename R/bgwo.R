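# Binary grey wolf optimizer (bGWO).
#
# Candidate solutions are bit vectors. Each wolf is pulled toward the
# three best solutions found so far (alpha, beta, delta): for each leader
# a continuous attraction step A*D is squashed through a steep sigmoid
# (cstep), thresholded against a uniform draw into a binary step (bstep),
# and OR-ed with the leader's bits to form one candidate; the three
# candidates are then combined by a stochastic uniform three-way
# crossover. The control scalar `a` decays linearly from 2 to 0 over the
# run, shifting the search from exploration to exploitation.
#
# Randomness contract (per wolf, per iteration, in this order):
#   for each leader in (alpha, beta, delta):
#     r1 (d draws), r2 (d draws)  -> A = 2 a r1 - a, C = 2 r2,
#                                    D = |C * leader - wolf|
#     rand (d draws)              -> bstep threshold
#   rand (d draws)                -> crossover source choice
#   one extra draw only if the all-zero repair triggers.
# Identical seeds therefore give bit-identical trajectories.

#' Linearly decaying GWO control scalar
#'
#' `a = 2 (1 - t / T)`: 2 at the first iteration, 0 in the limit `t = T`.
#'
#' @param t Iteration counter, `0 <= t <= T`.
#' @param T Total number of iterations (positive).
#' @return The scalar `a` in `[0, 2]`.
#' @export
gwo_a <- function(t, T) {
  if (T <= 0) stop("T must be positive")
  if (t < 0 || t > T) stop("t must lie in [0, T]")
  2 * (1 - t / T)
}

#' Draw per-dimension GWO coefficients for one leader
#'
#' Canonical GWO coefficient equations: `A = 2 a r1 - a`, `C = 2 r2` with
#' `r1, r2` fresh uniform draws per dimension, and leader distance
#' `D = |C * x_leader - x_wolf|`. Draws come from the current RNG stream
#' (two blocks of `d` uniforms, `r1` then `r2`).
#'
#' @param t,T Iteration counter and total iterations (see [gwo_a()]).
#' @param leader_bits,wolf_bits Binary vectors of equal length `d`.
#' @return List with `a`, and numeric vectors `A`, `C`, `D` of length `d`.
#' @export
update_coefficients <- function(t, T, leader_bits, wolf_bits) {
  if (length(leader_bits) != length(wolf_bits)) {
    stop("leader and wolf vectors must have equal length")
  }
  a <- gwo_a(t, T)
  d <- length(leader_bits)
  r1 <- runif(d)
  r2 <- runif(d)
  A <- 2 * a * r1 - a
  C <- 2 * r2
  D <- abs(C * leader_bits - wolf_bits)
  list(a = a, A = A, C = C, D = D)
}

#' Sigmoidal continuous step
#'
#' `cstep = 1 / (1 + exp(-10 (A D - 0.5)))`: a steep sigmoid centred at
#' `A D = 0.5`, strictly increasing in `A D`, with values in (0, 1).
#'
#' @param A,D Numeric vectors (recycled to a common length).
#' @return Numeric vector of step probabilities in (0, 1).
#' @export
cstep <- function(A, D) {
  1 / (1 + exp(-10 * (A * D - 0.5)))
}

#' Binary step
#'
#' Thresholds the continuous step against a uniform draw: 1 if
#' `cstep >= rand`, else 0. Over uniform draws the result is Bernoulli
#' with success probability `cstep`.
#'
#' @param cstep_value Continuous step values in (0, 1).
#' @param rand Uniform draws in `[0, 1)` of the same length.
#' @return Integer vector of bits.
#' @export
bstep <- function(cstep_value, rand) {
  as.integer(cstep_value >= rand)
}

#' Leader-guided binary candidate
#'
#' Combines a leader's bits with the binary steps: the candidate bit is 1
#' when `leader + bstep >= 1`, which on binary inputs is exactly the
#' elementwise OR.
#'
#' @param leader_bits,bsteps Binary vectors of equal length.
#' @return Integer vector of bits.
#' @export
leader_candidate <- function(leader_bits, bsteps) {
  if (length(leader_bits) != length(bsteps)) {
    stop("leader and bstep vectors must have equal length")
  }
  as.integer((leader_bits + bsteps) >= 1)
}

#' Stochastic three-way crossover
#'
#' Per dimension, the output bit is copied from the first parent if
#' `rand <= 1/3`, from the second if `1/3 < rand <= 2/3`, and from the
#' third otherwise, with a fresh uniform draw per dimension — each source
#' is chosen with probability 1/3.
#'
#' @param x1,x2,x3 Binary parent vectors of equal length `d`.
#' @param rand Optional vector of `d` uniform draws; by default drawn from
#'   the current RNG stream.
#' @return Integer vector of bits.
#' @export
crossover <- function(x1, x2, x3, rand = NULL) {
  d <- length(x1)
  if (length(x2) != d || length(x3) != d) {
    stop("parent vectors must have equal length")
  }
  if (is.null(rand)) rand <- runif(d)
  out <- x3
  out[rand <= 2 / 3] <- x2[rand <= 2 / 3]
  out[rand <= 1 / 3] <- x1[rand <= 1 / 3]
  as.integer(out)
}

#' Wrapper fitness of a feature subset
#'
#' The objective minimized by the optimizer:
#' `lambda * (1 - CV accuracy) + (1 - lambda) * n_selected / d`, i.e. a
#' trade-off between cross-validated classification error on the selected
#' columns and subset size. The all-zero subset is assigned the defined
#' fallback value `lambda` (classification error 1, zero sparsity cost)
#' and flagged, never an exception. Deterministic given the fold
#' assignment built by [make_fitness()].
#'
#' @param bits Binary vector over the columns of `x`.
#' @param x Numeric feature matrix (samples x features of one cluster).
#' @param y Class labels (factor), one per row.
#' @param folds Integer fold assignment per row (from `stratified_folds`).
#' @param lambda Error-vs-sparsity weight in (0, 1], default 0.99.
#' @param classifier Inner classifier; `"centroid"` (nearest class
#'   centroid, the fast linear default).
#' @return Scalar fitness (lower is better); attribute `"all_zero"` is
#'   `TRUE` for the fallback case.
#' @export
fitness_subset <- function(bits, x, y, folds, lambda = 0.99,
                           classifier = "centroid") {
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  d <- ncol(x)
  if (length(bits) != d) stop("bits length must match ncol(x)")
  n_sel <- sum(bits != 0)
  if (n_sel == 0L) {
    return(structure(lambda, all_zero = TRUE))
  }
  sel <- which(bits != 0)
  acc <- cv_accuracy_centroid(x[, sel, drop = FALSE], y, folds)
  lambda * (1 - acc) + (1 - lambda) * (n_sel / d)
}

# Cross-validated accuracy of the nearest-class-centroid linear classifier.
cv_accuracy_centroid <- function(xs, y, folds) {
  y <- as.factor(y)
  correct <- 0L
  for (f in unique(folds)) {
    tr <- folds != f
    te <- !tr
    cent <- rowsum(xs[tr, , drop = FALSE], y[tr], reorder = TRUE)
    cls <- rownames(cent)
    cent <- cent / as.vector(table(y[tr])[cls])
    # nearest centroid by squared Euclidean distance
    d2 <- outer(rep(1, sum(te)), rowSums(cent^2)) -
      2 * xs[te, , drop = FALSE] %*% t(cent)
    pred <- cls[max.col(-d2, ties.method = "first")]
    correct <- correct + sum(pred == as.character(y[te]))
  }
  correct / length(y)
}

#' Build a deterministic fitness closure for one feature cluster
#'
#' Fixes the stratified cross-validation folds once (seeded), so every
#' fitness evaluation during a run sees the same folds and the objective
#' is a deterministic function of the bit vector.
#'
#' @param x Feature matrix of the cluster (samples x features).
#' @param y Class labels.
#' @param lambda Error-vs-sparsity weight in (0, 1].
#' @param cv_folds Number of stratified folds (at least 2).
#' @param classifier Inner classifier name (see [fitness_subset()]).
#' @param seed Seed for the fold assignment.
#' @return A function `f(bits) -> fitness`.
#' @export
make_fitness <- function(x, y, lambda = 0.99, cv_folds = 3L,
                         classifier = "centroid", seed = NULL) {
  if (cv_folds < 2L) stop("cv_folds must be at least 2")
  y <- as.factor(y)
  folds <- stratified_folds(y, cv_folds, seed = seed)
  force(x)
  function(bits) fitness_subset(bits, x, y, folds, lambda = lambda,
                                classifier = classifier)
}

# Alpha/beta/delta selection: the three best DISTINCT bit vectors among
# the candidates. Distinctness and diversity matter for the OR-based
# update: every candidate built from a leader is a superset of it, so any
# bit shared by all three leaders is permanent in every descendant — a
# collapsed leader set freezes the search on its intersection. Alpha is
# the best solution (stable ties, incumbents first); beta and delta are
# chosen by fitness with ties broken toward the candidate farthest (in
# Hamming distance) from the leaders already chosen. Deterministic given
# the candidate order; duplicates fill the tail only when fewer than
# three distinct vectors exist.
select_leaders <- function(positions, fitness) {
  ord <- order(fitness)
  keys <- apply(positions[ord, , drop = FALSE], 1, paste, collapse = "")
  distinct <- ord[!duplicated(keys)]
  pick <- distinct[1]
  avail <- distinct[-1]
  while (length(pick) < 3L && length(avail) > 0L) {
    tied <- avail[fitness[avail] <= fitness[avail[1]] + 1e-12]
    if (length(tied) > 1L) {
      chosen <- positions[pick, , drop = FALSE]
      div <- vapply(tied, function(i) {
        sum(vapply(seq_len(nrow(chosen)), function(l) {
          sum(positions[i, ] != chosen[l, ])
        }, numeric(1)))
      }, numeric(1))
      best <- tied[which.max(div)]
    } else {
      best <- tied[1]
    }
    pick <- c(pick, best)
    avail <- setdiff(avail, best)
  }
  if (length(pick) < 3L) pick <- c(pick, setdiff(ord, pick))[1:3]
  list(positions = positions[pick, , drop = FALSE], fitness = fitness[pick])
}

#' Binary grey wolf optimization
#'
#' Minimizes `fitness_fn` over bit vectors of length `d`. The population
#' is initialized with independent fair-coin bits; each iteration builds,
#' for every wolf, one candidate per leader (sigmoid-thresholded binary
#' step OR-ed with the leader) and combines the three by stochastic
#' crossover. All-zero candidates are repaired by setting one uniformly
#' chosen bit. Leaders are elitist: alpha/beta/delta are the three best
#' distinct solutions evaluated so far (distinctness keeps the OR-based
#' update from freezing on a prematurely converged leader set), so the
#' alpha fitness is non-increasing.
#'
#' @param d Number of bits (positive).
#' @param fitness_fn Function mapping a bit vector to a scalar fitness
#'   (lower is better).
#' @param pop_size Population size (at least 3, default 10).
#' @param n_iter Number of iterations `T` (default 30).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   trajectories.
#' @return Object of class `binary_solution`: list with `bits` (the alpha
#'   bit vector), `fitness`, `n_selected`, `trace` (data frame with
#'   `iteration`, `alpha_fitness`, `alpha_n_selected`), and the call
#'   parameters.
#' @export
bgwo_optimize <- function(d, fitness_fn, pop_size = 10L, n_iter = 30L,
                          seed = NULL) {
  if (d < 1L) stop("d must be at least 1")
  if (pop_size < 3L) stop("pop_size must be at least 3 (three leaders)")
  if (n_iter < 1L) stop("n_iter must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  pop <- matrix(0L, nrow = pop_size, ncol = d)
  for (i in seq_len(pop_size)) {
    bits <- as.integer(runif(d) < 0.5)
    if (sum(bits) == 0L) bits[sample.int(d, 1L)] <- 1L  # repair at init too
    pop[i, ] <- bits
  }
  fit <- vapply(seq_len(pop_size), function(i) as.numeric(fitness_fn(pop[i, ])),
                numeric(1))

  sel <- select_leaders(pop, fit)
  leaders <- sel$positions
  leader_fit <- sel$fitness

  trace <- data.frame(iteration = integer(0), alpha_fitness = numeric(0),
                      alpha_n_selected = integer(0))
  for (t in seq_len(n_iter) - 1L) {
    a <- gwo_a(t, n_iter)
    for (i in seq_len(pop_size)) {
      wolf <- pop[i, ]
      cand <- matrix(0L, nrow = 3L, ncol = d)
      for (l in 1:3) {
        r1 <- runif(d)
        r2 <- runif(d)
        A <- 2 * a * r1 - a
        C <- 2 * r2
        D <- abs(C * leaders[l, ] - wolf)
        cs <- cstep(A, D)
        bs <- bstep(cs, runif(d))
        cand[l, ] <- leader_candidate(leaders[l, ], bs)
      }
      newpos <- crossover(cand[1, ], cand[2, ], cand[3, ])
      if (sum(newpos) == 0L) {
        newpos[sample.int(d, 1L)] <- 1L  # all-zero repair
      }
      pop[i, ] <- newpos
      fit[i] <- as.numeric(fitness_fn(newpos))
    }
    # elitist leader update over incumbents and the new population
    sel <- select_leaders(rbind(leaders, pop), c(leader_fit, fit))
    leaders <- sel$positions
    leader_fit <- sel$fitness
    trace <- rbind(trace, data.frame(iteration = t + 1L,
                                     alpha_fitness = leader_fit[1],
                                     alpha_n_selected = sum(leaders[1, ])))
  }

  structure(
    list(bits = leaders[1, ], fitness = leader_fit[1],
         n_selected = sum(leaders[1, ]), trace = trace,
         pop_size = pop_size, n_iter = n_iter, d = d, seed = seed),
    class = "binary_solution"
  )
}

#' @export
print.binary_solution <- function(x, ...) {
  cat("bGWO solution:", x$n_selected, "of", x$d, "bits set, fitness",
      format(x$fitness, digits = 6), "\n")
  invisible(x)
}
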