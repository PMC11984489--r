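# Shared numeric vocabulary: entropy, entropy production, and their gradients.

# entries below this are treated as numerically zero and rejected, since every
# model in the package takes logarithms of entries
.POSITIVITY_FLOOR <- 1e-300

.check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("%s must be numeric and finite", what), call. = FALSE)
  }
  invisible(x)
}

.check_strictly_positive <- function(x, what) {
  .check_finite(x, what)
  if (any(x < .POSITIVITY_FLOOR)) {
    stop(sprintf("%s must be strictly positive (min entry %.3g)", what, min(x)),
         call. = FALSE)
  }
  invisible(x)
}

#' Construct a strictly interior probability distribution
#'
#' A point on the interior of the `n`-simplex: all components strictly
#' positive and summing to one. Boundary states are rejected because the
#' entropy gradient diverges there and the flow laws take logarithms of the
#' components.
#'
#' @param p Numeric vector of probabilities.
#' @param tol Tolerance on `|sum(p) - 1|` (default `1e-12`).
#' @return A numeric vector of class `"distribution_state"`.
#' @examples
#' distribution_state(rep(1 / 4, 4))
#' @export
distribution_state <- function(p, tol = 1e-12) {
  .check_strictly_positive(p, "probability vector")
  if (length(p) < 2) stop("a distribution needs at least 2 states", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop(sprintf("probabilities must sum to 1 within %g (got %.15g)", tol, s),
         call. = FALSE)
  }
  structure(as.numeric(p), class = "distribution_state")
}

#' @export
print.distribution_state <- function(x, ...) {
  cat(sprintf("<distribution_state> n = %d, min p = %.4g, entropy = %.6g\n",
              length(x), min(x), shannon_entropy(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Construct a row-stochastic forward transition matrix
#'
#' An `N x N` matrix of strictly positive forward transition probabilities
#' `P[i, j]` with every row summing to one.
#'
#' @param P Numeric square matrix.
#' @param tol Tolerance on row sums (default `1e-12`).
#' @return A matrix of class `"transition_matrix"`.
#' @examples
#' transition_matrix(rbind(c(0.7, 0.3), c(0.4, 0.6)))
#' @export
transition_matrix <- function(P, tol = 1e-12) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P) || nrow(P) < 2) {
    stop("transition matrix must be square with N >= 2", call. = FALSE)
  }
  .check_strictly_positive(P, "transition matrix")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol)) {
    bad <- which.max(abs(rs - 1))
    stop(sprintf("row %d sums to %.15g; rows must sum to 1 within %g",
                 bad, rs[bad], tol), call. = FALSE)
  }
  structure(P, class = c("transition_matrix", "matrix"))
}

#' Construct a fixed backward-probability matrix
#'
#' `Q[i, j]` stores the backward transition probability conventionally
#' written \eqn{P_{ji}}: the chance of the reverse step from state `j` to
#' state `i`. Storing it index-matched to the forward matrix makes entropy
#' production an elementwise ratio `P / Q` and avoids a silent transpose bug.
#' `Q` is held fixed while the forward matrix evolves, and it is *not*
#' required to be row-stochastic; only strict positivity is enforced.
#'
#' @param Q Numeric square matrix of backward probabilities, index-matched to
#'   the forward matrix (`Q[i, j]` is the reverse of `P[i, j]`).
#' @return A matrix of class `"backward_matrix"`.
#' @examples
#' P <- transition_matrix(rbind(c(0.7, 0.3), c(0.4, 0.6)))
#' backward_matrix(t(P))  # transpose-matched reverse probabilities
#' @export
backward_matrix <- function(Q) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q) || nrow(Q) < 2) {
    stop("backward matrix must be square with N >= 2", call. = FALSE)
  }
  .check_strictly_positive(Q, "backward matrix")
  structure(Q, class = c("backward_matrix", "matrix"))
}

.as_prob_vector <- function(p) {
  if (inherits(p, "distribution_state")) return(as.numeric(p))
  as.numeric(distribution_state(p))
}

.as_positive_matrix <- function(M, what) {
  M <- unclass(as.matrix(M))
  .check_strictly_positive(M, what)
  M
}

#' Shannon information entropy
#'
#' Computes \eqn{S(p) = -K \sum_i p_i \ln p_i}, the information entropy of a
#' discrete distribution, in nats (times the constant `K`). The constant `K`
#' plays the role of the Boltzmann constant in the physical reading; the
#' default `K = 1` gives plain nats.
#'
#' @param p A [distribution_state()] or numeric probability vector.
#' @param K Positive scale constant (default 1).
#' @return Scalar entropy.
#' @examples
#' shannon_entropy(rep(1 / 4, 4))  # log(4)
#' @export
shannon_entropy <- function(p, K = 1) {
  stopifnot(is.numeric(K), length(K) == 1, K > 0)
  p <- .as_prob_vector(p)
  -K * sum(p * log(p))
}

#' Gradient of the Shannon entropy
#'
#' Component `i` is \eqn{\partial S / \partial p_i = -K(\ln p_i + 1)}, the
#' exact gradient of [shannon_entropy()]. The magnitude of this gradient
#' diverges as any component approaches zero, which is what repels the
#' entropy-ascent flow from the simplex boundary.
#'
#' @inheritParams shannon_entropy
#' @return Numeric vector of the same length as `p`.
#' @examples
#' entropy_gradient(rep(1 / 4, 4))  # all log(4) - 1
#' @export
entropy_gradient <- function(p, K = 1) {
  stopifnot(is.numeric(K), length(K) == 1, K > 0)
  p <- .as_prob_vector(p)
  -K * (log(p) + 1)
}

.check_pair <- function(P, Q) {
  P <- .as_positive_matrix(P, "forward matrix")
  Q <- .as_positive_matrix(Q, "backward matrix")
  if (!all(dim(P) == dim(Q))) {
    stop(sprintf("shape mismatch: forward is %dx%d, backward is %dx%d",
                 nrow(P), ncol(P), nrow(Q), ncol(Q)), call. = FALSE)
  }
  list(P = P, Q = Q)
}

#' Entropy production of a forward/backward transition pair
#'
#' The rate of entropy change of a Markovian system, measured as the
#' Kullback-Leibler-type sum
#' \deqn{\dot S = \sum_{i,j} P_{ij} \log(P_{ij} / Q_{ij}),}
#' where `Q[i, j]` stores the backward probability (see [backward_matrix()]).
#' It vanishes exactly at detailed balance (`Q` the transpose-match of a
#' symmetric `P`) and its magnitude measures the distance from detailed
#' balance. Natural logarithm throughout (nats). Because `Q` need not be
#' row-stochastic, the value is not guaranteed nonnegative in general.
#'
#' @param P Forward [transition_matrix()] (or plain positive matrix).
#' @param Q Backward [backward_matrix()] (or plain positive matrix),
#'   index-matched to `P`.
#' @return Scalar entropy production in nats per step.
#' @examples
#' P <- transition_matrix(rbind(c(0.7, 0.3), c(0.3, 0.7)))
#' entropy_production(P, backward_matrix(t(P)))  # 0: detailed balance
#' @export
entropy_production <- function(P, Q) {
  m <- .check_pair(P, Q)
  sum(m$P * (log(m$P) - log(m$Q)))
}

#' Kullback-Leibler divergence of a transition matrix from uniform
#'
#' Measures entropy production against a uniform baseline:
#' \deqn{\sum_{k,l} P_{kl} \log(P_{kl} / P^*),}
#' with \eqn{P^* = 1/N^2} by default (the uniform *joint* distribution over
#' `N x N` state pairs). Setting `reference = "row"` uses \eqn{P^* = 1/N}
#' (uniform rows); the two differ by exactly `N log N` because the rows of
#' `P` sum to one, and the choice does not affect the dynamics driven by this
#' functional (the baseline cancels from the row-centered gradient).
#'
#' @param P Forward [transition_matrix()].
#' @param reference `"joint"` (default, \eqn{P^* = 1/N^2}) or `"row"`
#'   (\eqn{P^* = 1/N}).
#' @return Scalar divergence in nats.
#' @examples
#' U <- transition_matrix(matrix(1 / 3, 3, 3))
#' kl_from_uniform(U)  # 3 * log(3)
#' @export
kl_from_uniform <- function(P, reference = c("joint", "row")) {
  reference <- match.arg(reference)
  P <- .as_positive_matrix(P, "transition matrix")
  N <- nrow(P)
  p_star <- if (reference == "joint") 1 / N^2 else 1 / N
  sum(P * (log(P) - log(p_star)))
}

#' Maximum deviation from detailed balance
#'
#' Returns \eqn{\max_{i,j} |P_{ij} - Q_{ij}|} where `Q[i, j]` stores the
#' backward probability of the `i -> j` step. Zero exactly when the pair is
#' in detailed balance. A diagnostic, reported along every balance-model
#' trajectory.
#'
#' @inheritParams entropy_production
#' @return Scalar residual.
#' @export
balance_residual <- function(P, Q) {
  m <- .check_pair(P, Q)
  max(abs(m$P - m$Q))
}

#' Entropy metrics report for a transition-matrix pair
#'
#' Bundles the diagnostics of a forward matrix (and optionally a backward
#' matrix) into one list: the total row entropy
#' \eqn{-K \sum_{ij} P_{ij} \ln P_{ij}} (the sum over rows of each row's
#' Shannon entropy), the entropy production relative to `Q` (if given), the
#' divergence from the uniform baseline, and the balance residual.
#'
#' @inheritParams entropy_production
#' @param K Positive entropy scale constant (default 1).
#' @return A list of class `"entropy_report"` with elements `entropy`,
#'   `entropy_production` (`NA` if `Q` missing), `kl_from_uniform`,
#'   `balance_residual` (`NA` if `Q` missing), and `metadata`
#'   (`N`, `K`, `log_base`).
#' @export
entropy_report <- function(P, Q = NULL, K = 1) {
  P <- .as_positive_matrix(P, "forward matrix")
  rep <- list(
    entropy = -K * sum(P * log(P)),
    entropy_production = NA_real_,
    kl_from_uniform = kl_from_uniform(P),
    balance_residual = NA_real_,
    metadata = list(N = nrow(P), K = K, log_base = "natural")
  )
  if (!is.null(Q)) {
    rep$entropy_production <- entropy_production(P, Q)
    rep$balance_residual <- balance_residual(P, Q)
  }
  class(rep) <- "entropy_report"
  rep
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("<entropy_report> N = %d, K = %g (natural log)\n",
              x$metadata$N, x$metadata$K))
  cat(sprintf("  entropy            : %.8g\n", x$entropy))
  cat(sprintf("  entropy_production : %.8g\n", x$entropy_production))
  cat(sprintf("  kl_from_uniform    : %.8g\n", x$kl_from_uniform))
  cat(sprintf("  balance_residual   : %.8g\n", x$balance_residual))
  invisible(x)
}
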