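# Seeded synthetic fixtures: every model input the package needs can be
# generated deterministically, so all tests and demos run with no external
# data. Generators restore the caller's RNG state.

.with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Random strictly interior distribution
#'
#' Draws a point from a flat Dirichlet on the `n`-simplex, then mixes in a
#' floor so every coordinate is at least `min_p`. The construction is
#' exchangeable across coordinates (each coordinate has mean `1/n`) and a
#' pure function of `(n, seed)`.
#'
#' @param n Number of states (>= 2).
#' @param seed Integer seed.
#' @param min_p Guaranteed minimum coordinate (default `1e-3`); requires
#'   `n * min_p < 1`.
#' @return A [distribution_state()].
#' @export
random_interior_distribution <- function(n, seed, min_p = 1e-3) {
  if (n < 2) .sg_stop("sg_usage_error", "n must be >= 2 (got %d)", n)
  if (n * min_p >= 1) {
    .sg_stop("sg_usage_error", "min_p = %g infeasible for n = %d", min_p, n)
  }
  .with_seed(seed, {
    e <- stats::rexp(n)
    p <- min_p + (1 - n * min_p) * e / sum(e)
    distribution_state(p / sum(p))
  })
}

#' Random feasible linear constraint set with interior feasible point
#'
#' Generates `m` random Gaussian constraint rows and an interior point
#' `p_f`, then sets the right-hand side to `b = A p_f`, so the feasible set
#' is guaranteed to intersect the open simplex. The normalization row is
#' appended by [constraint_set()]. With `m = 0` the result is the
#' normalization-only constraint set.
#'
#' @param n Number of states (>= 2).
#' @param m Number of constraints before the normalization row
#'   (`0 <= m <= n - 2` so that at least one degree of freedom remains).
#' @param seed Integer seed.
#' @return List with `constraints` (a [constraint_set()]) and
#'   `feasible_point` (a [distribution_state()] satisfying them).
#' @export
random_constraint_set <- function(n, m, seed) {
  if (n < 2) .sg_stop("sg_usage_error", "n must be >= 2")
  if (m < 0 || m > n - 2) {
    .sg_stop("sg_usage_error",
             "m = %d infeasible: need 0 <= m <= n - 2 = %d before normalization",
             m, n - 2)
  }
  .with_seed(seed, {
    e <- stats::rexp(n)
    p_f <- 1e-3 + (1 - n * 1e-3) * e / sum(e)
    p_f <- p_f / sum(p_f)
    if (m == 0) {
      A <- matrix(1, nrow = 1, ncol = n)
      b <- 1
    } else {
      A <- matrix(stats::rnorm(m * n), nrow = m, ncol = n)
      b <- as.numeric(A %*% p_f)
    }
    list(constraints = constraint_set(A, b),
         feasible_point = distribution_state(p_f))
  })
}

#' Mean-position ("center of mass") constraint instance
#'
#' The classic one-moment instance: cells at positions `q` with prescribed
#' mean position `sum(p * q) = M`, plus normalization. Feasible with an
#' interior point whenever `min(q) < M < max(q)`.
#'
#' @param q Numeric vector of cell positions (default `1:n` not assumed;
#'   pass explicitly).
#' @param M Prescribed mean position.
#' @return A [constraint_set()].
#' @examples
#' C <- center_of_mass_constraints(1:4, M = 2)
#' maxent_oracle(C)
#' @export
center_of_mass_constraints <- function(q, M) {
  q <- as.numeric(q)
  .check_finite(q, "positions q")
  if (length(unique(q)) < 2) {
    .sg_stop("sg_usage_error", "positions q must not be constant")
  }
  if (M <= min(q) || M >= max(q)) {
    .sg_stop("sg_usage_error",
             "M = %g has no interior feasible point: need min(q) < M < max(q)", M)
  }
  constraint_set(matrix(q, nrow = 1), b = M)
}

#' Random strictly positive row-stochastic matrix
#'
#' Each row is an independent flat Dirichlet draw mixed with a uniform
#' floor, so every entry is at least `min_entry` and each row sums to one
#' exactly (up to float).
#'
#' @param N Number of states (>= 2).
#' @param seed Integer seed.
#' @param min_entry Guaranteed minimum entry (default `1e-3`); requires
#'   `min_entry < 1/N`.
#' @return A [transition_matrix()].
#' @export
random_stochastic_matrix <- function(N, seed, min_entry = 1e-3) {
  if (N < 2) .sg_stop("sg_usage_error", "N must be >= 2")
  if (min_entry <= 0 || min_entry >= 1 / N) {
    .sg_stop("sg_usage_error", "min_entry = %g infeasible for N = %d", min_entry, N)
  }
  .with_seed(seed, {
    E <- matrix(stats::rexp(N * N), N, N)
    P <- E / rowSums(E)
    P <- min_entry + (1 - N * min_entry) * P
    transition_matrix(P / rowSums(P))
  })
}

#' Exact detailed-balance forward/backward pair
#'
#' Builds a symmetric strictly positive row-stochastic matrix `P` (random
#' symmetric seed matrix, symmetric Sinkhorn scaling to doubly stochastic,
#' final symmetrization) and the transpose-matched backward matrix
#' `Q = t(P)`. Since `P` is symmetric, `Q = P` elementwise and the entropy
#' production of the pair is zero to rounding: an exact equilibrium of the
#' backward-variant flow.
#'
#' @param N Number of states (>= 2).
#' @param seed Integer seed.
#' @param max_iter Sinkhorn iteration cap (default 500).
#' @param tol Row-sum tolerance driven to `tol` before symmetrization
#'   (default `1e-15`).
#' @return List with `P` (a [transition_matrix()]) and `Q`
#'   (a [backward_matrix()]).
#' @export
detailed_balance_pair <- function(N, seed, max_iter = 500L, tol = 1e-15) {
  if (N < 2) .sg_stop("sg_usage_error", "N must be >= 2")
  .with_seed(seed, {
    R <- matrix(stats::runif(N * N, min = 0.2, max = 1), N, N)
    S <- (R + t(R)) / 2
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      r <- rowSums(S)
      if (max(abs(r - 1)) < tol) {
        ok <- TRUE
        break
      }
      # symmetric Sinkhorn scaling: divide by sqrt(r_i r_j)
      S <- S / sqrt(outer(r, r))
    }
    if (!ok) {
      .sg_stop("sg_solver_error",
               "doubly-stochastic rescaling did not converge in %d iterations", max_iter)
    }
    S <- (S + t(S)) / 2
    S <- S / rowSums(S)
    list(P = transition_matrix(S), Q = backward_matrix(t(S)))
  })
}

#' Perturb a forward matrix away from detailed balance
#'
#' Adds a seeded zero-row-sum perturbation of infinity-norm `epsilon` to
#' the forward matrix only; the backward matrix is returned untouched
#' (frozen). Zero row sums keep the perturbed matrix exactly
#' row-stochastic with no renormalization, so the entropy production of
#' the perturbed pair is a clean second-order (O(epsilon^2)) quantity when
#' the pair started at detailed balance.
#'
#' @param P Forward [transition_matrix()].
#' @param Q Backward matrix, passed through unchanged.
#' @param epsilon Perturbation infinity-norm (>= 0); must leave all entries
#'   positive.
#' @param seed Integer seed.
#' @return List with the perturbed `P` and the unchanged `Q`.
#' @export
perturb_pair <- function(P, Q, epsilon, seed) {
  P <- .as_positive_matrix(transition_matrix(P), "forward matrix")
  if (epsilon < 0) .sg_stop("sg_usage_error", "epsilon must be >= 0")
  if (epsilon == 0) {
    return(list(P = transition_matrix(P), Q = Q))
  }
  N <- nrow(P)
  D <- .with_seed(seed, {
    Z <- matrix(stats::rnorm(N * N), N, N)
    Z - rowMeans(Z)  # zero row sums
  })
  D <- D / max(abs(D)) * epsilon
  trial <- P + D
  if (min(trial) <= 0) {
    .sg_stop("sg_usage_error",
             "epsilon = %g too large: perturbed matrix loses positivity (min %.3g)",
             epsilon, min(trial))
  }
  list(P = transition_matrix(trial, tol = 1e-12), Q = Q)
}
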