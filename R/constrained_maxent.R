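# Speed-gradient flow of Shannon entropy on the simplex under linear
# equality constraints A p = b, plus an independent dual-Newton
# maximum-entropy solver used as the convergence oracle.

# relative tolerance on the singular values of A A^T below which the
# constraint matrix is declared rank-deficient
.RANK_TOL <- 1e-10

.sg_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "sg_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

#' Construct a linear constraint set on the simplex
#'
#' Encodes the equality constraints `A p = b` under which the entropy flow
#' evolves. The normalization constraint `sum(p) = 1` is part of the
#' constraint system by construction: if the all-ones direction is not
#' already in the row space of `A`, a row of ones (with right-hand side 1)
#' is appended automatically. Folding normalization into `A` makes the
#' projected flow conserve total mass exactly.
#'
#' `A` must have full row rank after this augmentation: rank deficiency is
#' detected when the smallest singular value of `A A^T` falls below
#' `1e-10` times the largest, and is an error (linearly dependent
#' constraints should be removed, not silently tolerated).
#'
#' @param A Numeric matrix with one row per constraint (m x n).
#' @param b Numeric right-hand side, length `nrow(A)`.
#' @return An object of class `"constraint_set"`: a list with elements `A`
#'   (augmented matrix), `b` (augmented right-hand side), `n`, `m` (rows of
#'   the augmented system), and `includes_normalization` (always `TRUE`;
#'   records whether the ones-row was found or appended).
#' @examples
#' # mean-position ("center of mass") constraint sum(p * q) = M on 4 states
#' C <- constraint_set(matrix(1:4, nrow = 1), b = 2)
#' C$m  # 2: the given row plus the appended normalization row
#' @export
constraint_set <- function(A, b) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  .check_finite(A, "constraint matrix A")
  .check_finite(b, "right-hand side b")
  if (nrow(A) != length(b)) {
    .sg_stop("sg_usage_error", "A has %d rows but b has length %d",
             nrow(A), length(b))
  }
  n <- ncol(A)
  if (n < 2) .sg_stop("sg_usage_error", "constraints need n >= 2 states")
  ones <- rep(1, n)
  # is the all-ones direction already in the row space of A?
  ls <- tryCatch(qr.solve(t(A), ones, tol = 1e-12), error = function(e) NULL)
  ones_in_rowspace <- !is.null(ls) &&
    max(abs(crossprod(A, ls) - ones)) < 1e-10
  appended <- FALSE
  if (ones_in_rowspace) {
    implied_sum <- sum(ls * b)
    if (abs(implied_sum - 1) > 1e-8) {
      .sg_stop("sg_usage_error",
               "constraints imply sum(p) = %.12g, inconsistent with a probability vector",
               implied_sum)
    }
  } else {
    A <- rbind(A, ones)
    b <- c(b, 1)
    appended <- TRUE
  }
  rownames(A) <- NULL
  m <- nrow(A)
  if (m > n) {
    .sg_stop("sg_usage_error",
             "%d independent constraints on %d states leave no feasible freedom", m, n)
  }
  d <- svd(A, nu = 0, nv = 0)$d
  # singular values of A A^T are d^2
  if (min(d)^2 <= .RANK_TOL * max(d)^2) {
    .sg_stop("sg_rank_error",
             "constraint matrix is rank-deficient: smallest singular value of AA^T is below %g x largest",
             .RANK_TOL)
  }
  structure(list(A = A, b = b, n = n, m = m,
                 includes_normalization = TRUE,
                 normalization_appended = appended),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("<constraint_set> m = %d constraints on n = %d states (normalization %s)\n",
              x$m, x$n,
              if (x$normalization_appended) "appended" else "already in row space"))
  invisible(x)
}

.as_constraint_set <- function(C) {
  if (inherits(C, "constraint_set")) return(C)
  .sg_stop("sg_usage_error", "expected a constraint_set object")
}

#' Orthogonal projector onto the null space of a constraint matrix
#'
#' Returns \eqn{P_A = I_n - A^T (A A^T)^{-1} A}, the matrix projecting any
#' direction onto the subspace `{u : A u = 0}` of motions compatible with
#' the constraints. It is symmetric, idempotent, and annihilates the rows
#' of `A`.
#'
#' @param A A numeric constraint matrix with full row rank, or a
#'   [constraint_set()] (whose augmented matrix is used).
#' @return An `n x n` projection matrix.
#' @examples
#' P <- projection_matrix(matrix(1, nrow = 1, ncol = 3))
#' max(abs(P - (diag(3) - 1 / 3)))  # centering projector
#' @export
projection_matrix <- function(A) {
  if (inherits(A, "constraint_set")) A <- A$A
  A <- as.matrix(A)
  .check_finite(A, "constraint matrix A")
  d <- svd(A, nu = 0, nv = 0)$d
  if (min(d)^2 <= .RANK_TOL * max(d)^2) {
    .sg_stop("sg_rank_error",
             "rank-deficient constraint matrix (AA^T singular beyond relative tolerance %g)",
             .RANK_TOL)
  }
  G <- A %*% t(A)
  diag(ncol(A)) - t(A) %*% solve(G, A)
}

#' Settings for the constrained entropy flow
#'
#' @param gamma Positive gain: the flow is `dp/dt = gamma * P_A grad S`.
#'   `gamma` rescales time only; terminal states do not depend on it.
#' @param K Positive entropy scale constant passed to [shannon_entropy()].
#' @param t_end Integration horizon.
#' @param rtol,atol Relative/absolute local error tolerances of the adaptive
#'   Runge-Kutta integrator.
#' @param convergence_tol Stop when the 2-norm of the projected entropy
#'   gradient falls below this threshold.
#' @param positivity_floor Trial steps taking any component at or below this
#'   floor are rejected and retried with a halved step.
#' @param max_step_shrink Maximum consecutive step halvings before the run
#'   reports floor stagnation.
#' @param literal_eq9 If `TRUE`, use the printed-sign field
#'   `gamma * P_A (log p + 1)` (which *descends* the entropy) instead of the
#'   entropy-ascent field `gamma * P_A grad S`. For comparison only.
#' @return A list of class `"flow_settings"`.
#' @export
flow_settings <- function(gamma = 1, K = 1, t_end = 100,
                          rtol = 1e-8, atol = 1e-10,
                          convergence_tol = 1e-8,
                          positivity_floor = 1e-12,
                          max_step_shrink = 40L,
                          literal_eq9 = FALSE) {
  stopifnot(gamma > 0, K > 0, t_end > 0, rtol > 0, atol > 0,
            convergence_tol > 0, positivity_floor > 0,
            max_step_shrink >= 1, is.logical(literal_eq9))
  structure(list(gamma = gamma, K = K, t_end = t_end, rtol = rtol,
                 atol = atol, convergence_tol = convergence_tol,
                 positivity_floor = positivity_floor,
                 max_step_shrink = as.integer(max_step_shrink),
                 literal_eq9 = literal_eq9),
            class = "flow_settings")
}

#' Speed-gradient vector field of the constrained entropy flow
#'
#' The admissible direction of fastest entropy growth:
#' \deqn{u = \gamma \, P_A \, \nabla S(p),}
#' the entropy gradient projected onto the null space of the constraint
#' matrix and scaled by the gain. At the constrained entropy maximizer the
#' projected gradient (hence `u`) vanishes. The result always satisfies
#' `A u = 0`, so the flow moves along the feasible affine subspace.
#'
#' @param p A [distribution_state()] or interior probability vector.
#' @param C A [constraint_set()].
#' @param settings A [flow_settings()] (supplies `gamma`, `K`, and the
#'   `literal_eq9` switch).
#' @return Numeric vector `u` of length `n`.
#' @export
speed_gradient_field <- function(p, C, settings = flow_settings()) {
  p <- .as_prob_vector(p)
  C <- .as_constraint_set(C)
  if (length(p) != C$n) {
    .sg_stop("sg_usage_error", "state has %d components, constraints expect %d",
             length(p), C$n)
  }
  PA <- projection_matrix(C)
  g <- if (settings$literal_eq9) log(p) + 1 else entropy_gradient(p, settings$K)
  as.numeric(settings$gamma * (PA %*% g))
}

#' Euclidean projection onto the feasible affine subspace
#'
#' Returns the closest point (in the 2-norm) to `p` on `{x : A x = b}`:
#' \eqn{p - A^T (A A^T)^{-1} (A p - b)}. Used for drift correction after
#' every accepted integrator step; idempotent. Note the result is affine
#' feasibility only -- it may have negative components if `p` is far from
#' the simplex.
#'
#' @param p Numeric vector.
#' @param C A [constraint_set()].
#' @return Numeric vector satisfying `A x = b` to machine precision.
#' @export
feasibility_project <- function(p, C) {
  C <- .as_constraint_set(C)
  p <- as.numeric(p)
  .check_finite(p, "p")
  if (length(p) != C$n) {
    .sg_stop("sg_usage_error", "state has %d components, constraints expect %d",
             length(p), C$n)
  }
  A <- C$A
  as.numeric(p - t(A) %*% solve(A %*% t(A), A %*% p - C$b))
}

#' Integrate the constrained entropy flow
#'
#' Evolves `dp/dt = gamma * P_A grad S(p)` from a feasible interior start
#' with an adaptive Runge-Kutta integrator, re-projecting every accepted
#' state onto `{A p = b}` to cancel drift and rejecting (halving) any step
#' that would cross the positivity floor. The run terminates when the
#' projected-gradient norm drops below `convergence_tol`, at `t_end`, or on
#' floor stagnation.
#'
#' Along the exact flow, \eqn{dS/dt = \gamma \lVert P_A \nabla S \rVert^2
#' \ge 0}: entropy is nondecreasing and the trajectory converges to the
#' unique constrained maximum-entropy (Gibbs) state, which can be checked
#' against the independent [maxent_oracle()].
#'
#' @param p0 Feasible interior start: `A p0 = b` within `1e-8`.
#' @param C A [constraint_set()].
#' @param settings A [flow_settings()].
#' @return An object of class `"sg_trajectory"`: list with `times`,
#'   `states` (one row per stored sample), per-sample diagnostics
#'   `entropy`, `constraint_residual` (`max |A p - b|`), `grad_norm`
#'   (projected-gradient 2-norm), the termination `status`
#'   (`"converged"`, `"t_end"`, or `"floor_stagnation"`), `converged`
#'   flag, and the inputs.
#' @examples
#' C <- constraint_set(matrix(1:4, nrow = 1), b = 2)
#' fix <- random_constraint_set(4, 0, seed = 1)  # normalization only
#' traj <- evolve(rep(0.25, 4) + c(0.1, -0.1, 0.05, -0.05), C = fix$constraints,
#'                settings = flow_settings(t_end = 50))
#' terminal_state(traj)  # uniform
#' @export
evolve <- function(p0, C, settings = flow_settings()) {
  C <- .as_constraint_set(C)
  p0 <- .as_prob_vector(p0)
  if (length(p0) != C$n) {
    .sg_stop("sg_usage_error", "p0 has %d components, constraints expect %d",
             length(p0), C$n)
  }
  res0 <- max(abs(C$A %*% p0 - C$b))
  if (res0 > 1e-8) {
    .sg_stop("sg_usage_error",
             "p0 is infeasible: max |A p0 - b| = %.3g exceeds 1e-8", res0)
  }
  PA <- projection_matrix(C)
  A <- C$A
  G <- A %*% t(A)
  K <- settings$K
  sgn <- if (settings$literal_eq9) 1 else -1  # field = gamma * PA %*% sgn*K*(log p + 1) with sgn=-1 the true gradient
  gamma <- settings$gamma
  field <- function(p) {
    as.numeric(gamma * (PA %*% (sgn * K * (log(p) + 1))))
  }
  project <- function(p) {
    as.numeric(p - t(A) %*% solve(G, A %*% p - C$b))
  }
  proj_grad_norm <- function(p) {
    sqrt(sum((PA %*% (-K * (log(p) + 1)))^2))
  }
  stop_fn <- function(p) proj_grad_norm(p) < settings$convergence_tol
  out <- .sg_integrate(p0, field, t_end = settings$t_end,
                       rtol = settings$rtol, atol = settings$atol,
                       project = project, floor = settings$positivity_floor,
                       max_halvings = settings$max_step_shrink,
                       stop_fn = stop_fn)
  states <- out$states
  entropy <- apply(states, 1, function(p) -K * sum(p * log(p)))
  resid <- apply(states, 1, function(p) max(abs(A %*% p - C$b)))
  gnorm <- apply(states, 1, proj_grad_norm)
  structure(list(times = out$times, states = states,
                 entropy = entropy, constraint_residual = resid,
                 grad_norm = gnorm, status = out$status,
                 converged = out$status == "converged",
                 n_steps = out$n_steps,
                 constraints = C, settings = settings),
            class = "sg_trajectory")
}

#' @export
print.sg_trajectory <- function(x, ...) {
  cat(sprintf("<sg_trajectory> %d samples, t in [0, %.4g], status: %s\n",
              length(x$times), max(x$times), x$status))
  cat(sprintf("  entropy %.8g -> %.8g; final grad norm %.3g; max residual %.3g\n",
              x$entropy[1], x$entropy[length(x$entropy)],
              x$grad_norm[length(x$grad_norm)], max(x$constraint_residual)))
  invisible(x)
}

#' Terminal state of a trajectory
#'
#' @param traj An `"sg_trajectory"` from [evolve()].
#' @return The last stored state as a [distribution_state()].
#' @export
terminal_state <- function(traj) {
  stopifnot(inherits(traj, "sg_trajectory"))
  distribution_state(traj$states[nrow(traj$states), ], tol = 1e-6)
}

#' Independent maximum-entropy (Gibbs) solver
#'
#' Computes the unique maximizer of the Shannon entropy over
#' `{p : A p = b}` intersected with the open simplex, by Newton's method on
#' the smooth convex dual
#' \deqn{d(\lambda) = \sum_i \exp\big((A^T\lambda)_i - 1\big) - b^T\lambda,}
#' whose stationary point gives the exponential-family solution
#' \eqn{p_i = \exp((A^T\lambda)_i - 1)}. This route shares no code with the
#' speed-gradient flow and serves as its convergence oracle.
#'
#' @param C A [constraint_set()].
#' @param tol Stop when `max |A p - b|` falls below this (default `1e-12`).
#' @param max_iter Maximum Newton iterations.
#' @return A [distribution_state()] with attribute `"lambda"` (the dual
#'   vector, one multiplier per augmented constraint row) and `"iterations"`.
#' @examples
#' C <- constraint_set(matrix(1:4, nrow = 1), b = 2)
#' p <- maxent_oracle(C)
#' sum(p * 1:4)  # 2
#' @export
maxent_oracle <- function(C, tol = 1e-12, max_iter = 200L) {
  C <- .as_constraint_set(C)
  A <- C$A
  b <- C$b
  lambda <- numeric(C$m)
  dual <- function(l) sum(exp(crossprod(A, l) - 1)) - sum(b * l)
  d_cur <- dual(lambda)
  for (it in seq_len(max_iter)) {
    p <- as.numeric(exp(crossprod(A, lambda) - 1))
    g <- as.numeric(A %*% p - b)
    if (max(abs(g)) < tol) {
      p <- p / sum(p)
      out <- distribution_state(p)
      attr(out, "lambda") <- lambda
      attr(out, "iterations") <- it
      return(out)
    }
    H <- A %*% (p * t(A))
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      .sg_stop("sg_solver_error",
               "singular dual Hessian: constraint set likely infeasible or boundary-only")
    }
    # backtracking line search on the convex dual (descent is guaranteed
    # for small enough alpha; the slack term absorbs rounding at optimum)
    alpha <- 1
    repeat {
      d_new <- dual(lambda + alpha * step)
      if (is.finite(d_new) && d_new < d_cur + 1e-12 * (1 + abs(d_cur))) break
      alpha <- alpha / 2
      if (alpha < 1e-12) {
        .sg_stop("sg_solver_error",
                 "dual Newton stalled: constraint set likely infeasible or boundary-only")
      }
    }
    lambda <- lambda + alpha * step
    d_cur <- dual(lambda)
  }
  .sg_stop("sg_solver_error",
           "dual Newton did not converge in %d iterations (infeasible constraints?)",
           max_iter)
}
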