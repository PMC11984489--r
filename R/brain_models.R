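# Detailed-balance-breaking dynamics on row-stochastic transition matrices.
#
# Two speed-gradient models for how a coarse-grained brain network could
# drive its entropy production upward: the "backward" variant ascends the
# forward/backward Kullback-Leibler divergence with the backward
# probabilities frozen; the "uniform" variant ascends the divergence from a
# uniform baseline. Each exists in continuous time (a matrix ODE) and
# sampled time (a unit-step map).

#' Unconstrained gradient of the entropy production
#'
#' The derivative of [entropy_production()] with respect to each forward
#' entry, holding the backward matrix fixed: since exactly one term of the
#' double sum depends on `P[i, j]`,
#' \deqn{G_{ij} = \log(P_{ij} / Q_{ij}) + 1.}
#'
#' @inheritParams entropy_production
#' @return An `N x N` numeric matrix.
#' @export
production_gradient <- function(P, Q) {
  m <- .check_pair(P, Q)
  log(m$P) - log(m$Q) + 1
}

#' Row-normalization Lagrange multipliers of the balance-breaking flow
#'
#' The per-row multipliers that make the gradient ascent of entropy
#' production conserve row sums:
#' \deqn{\lambda_i = 1 + \frac{1}{N}\sum_l \log(P_{il} / Q_{il}),}
#' i.e. the row means of [production_gradient()]. Subtracting
#' \eqn{\lambda_i} from row `i` of the gradient gives a matrix whose rows
#' sum to zero exactly. At detailed balance every multiplier equals 1.
#'
#' @inheritParams entropy_production
#' @return Numeric vector of length `N`.
#' @export
lagrange_multipliers <- function(P, Q) {
  m <- .check_pair(P, Q)
  1 + rowMeans(log(m$P) - log(m$Q))
}

#' Continuous balance-breaking field (backward-referenced variant)
#'
#' The law of fastest entropy-production growth compatible with row
#' normalization:
#' \deqn{\dot P_{ij} = \gamma\Big[\log\frac{P_{ij}}{Q_{ij}}
#'   - \frac{1}{N}\sum_l \log\frac{P_{il}}{Q_{il}}\Big],}
#' i.e. the row-centered log-ratio of forward to (frozen) backward
#' probabilities, scaled by the gain. Every row of the result sums to zero,
#' so the flow preserves row-stochasticity; the field vanishes exactly at
#' detailed balance.
#'
#' @inheritParams entropy_production
#' @param gamma Positive gain (activity) coefficient.
#' @return An `N x N` matrix with zero row sums.
#' @export
balance_field <- function(P, Q, gamma = 1) {
  stopifnot(gamma > 0)
  m <- .check_pair(P, Q)
  H <- log(m$P) - log(m$Q)
  gamma * (H - rowMeans(H))
}

#' Continuous balance-breaking field (uniform-baseline variant)
#'
#' Ascends [kl_from_uniform()] instead of the forward/backward divergence:
#' \deqn{\dot P_{ij} = \gamma\Big[\log\frac{P_{ij}}{P^*}
#'   - \frac{1}{N}\sum_l \log\frac{P_{il}}{P^*}\Big],}
#' with \eqn{P^* = 1/N^2} the uniform joint baseline. The baseline cancels
#' from the row-centering, so the dynamics are independent of the choice of
#' \eqn{P^*}; the `p_star` argument exists to make that cancellation
#' checkable. The field vanishes exactly on matrices with uniform rows.
#'
#' @param P Forward [transition_matrix()].
#' @param gamma Positive gain (activity) coefficient.
#' @param p_star Baseline probability (default `1/N^2`); any positive value
#'   yields the identical field.
#' @return An `N x N` matrix with zero row sums.
#' @export
uniform_field <- function(P, gamma = 1, p_star = NULL) {
  stopifnot(gamma > 0)
  P <- .as_positive_matrix(P, "transition matrix")
  N <- nrow(P)
  if (is.null(p_star)) p_star <- 1 / N^2
  stopifnot(p_star > 0)
  H <- log(P) - log(p_star)
  gamma * (H - rowMeans(H))
}

#' Settings for the balance-breaking models
#'
#' @param gamma Positive gain (activity) coefficient. In continuous mode it
#'   rescales time; in sampled mode it is the step size of the unit-time map
#'   and must be small for the map to track the flow.
#' @param variant `"backward"` (ascend forward/backward entropy production,
#'   requires a backward matrix `Q`) or `"uniform"` (ascend the divergence
#'   from the uniform baseline).
#' @param mode `"sampled"` (iterate the discrete map) or `"continuous"`
#'   (integrate the matrix ODE).
#' @param n_steps Number of sampled-time iterations (sampled mode).
#' @param t_end Integration horizon (continuous mode).
#' @param rtol,atol Integrator tolerances (continuous mode).
#' @param positivity_floor Entries at or below this floor trigger the
#'   step-halving safeguard.
#' @param max_step_shrink Maximum halvings (of the integration step, or of
#'   the effective gain in sampled mode) before stagnation is declared.
#' @return A list of class `"balance_settings"`.
#' @export
balance_settings <- function(gamma = 0.01,
                             variant = c("backward", "uniform"),
                             mode = c("sampled", "continuous"),
                             n_steps = 100L, t_end = 1,
                             rtol = 1e-8, atol = 1e-10,
                             positivity_floor = 1e-12,
                             max_step_shrink = 40L) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  stopifnot(gamma > 0, n_steps >= 1, t_end > 0, rtol > 0, atol > 0,
            positivity_floor > 0, max_step_shrink >= 1)
  structure(list(gamma = gamma, variant = variant, mode = mode,
                 n_steps = as.integer(n_steps), t_end = t_end,
                 rtol = rtol, atol = atol,
                 positivity_floor = positivity_floor,
                 max_step_shrink = as.integer(max_step_shrink)),
            class = "balance_settings")
}

.balance_field_for <- function(settings, Q) {
  if (settings$variant == "backward") {
    if (is.null(Q)) {
      .sg_stop("sg_usage_error",
               "the backward variant needs a backward matrix Q")
    }
    logQ <- log(.as_positive_matrix(Q, "backward matrix"))
    function(P, gamma) {
      H <- log(P) - logQ
      gamma * (H - rowMeans(H))
    }
  } else {
    function(P, gamma) {
      H <- log(P)
      gamma * (H - rowMeans(H))
    }
  }
}

.goal_for <- function(settings, Q) {
  if (settings$variant == "backward") {
    logQ <- log(.as_positive_matrix(Q, "backward matrix"))
    function(P) sum(P * (log(P) - logQ))
  } else {
    function(P) {
      N <- nrow(P)
      sum(P * (log(P) + log(N^2)))
    }
  }
}

#' One sampled-time step of a balance-breaking map
#'
#' Applies the unit-step map `P <- P + F(P)` where `F` is the chosen
#' variant's field with the gain folded in. The increment has zero row
#' sums, so row-stochasticity is preserved exactly. If the trial matrix
#' would cross the positivity floor, the effective gain is transiently
#' halved for this step (up to `max_step_shrink` times); the gain actually
#' used is recorded in the `"effective_gamma"` attribute.
#'
#' @param P Forward [transition_matrix()].
#' @param settings A [balance_settings()] (its `mode` is ignored here).
#' @param Q Backward matrix, required for the `"backward"` variant.
#' @return The stepped [transition_matrix()] with attribute
#'   `"effective_gamma"`.
#' @export
step_sampled <- function(P, settings = balance_settings(), Q = NULL) {
  P <- .as_positive_matrix(P, "transition matrix")
  if (!is.null(Q) && !all(dim(as.matrix(Q)) == dim(P))) {
    .sg_stop("sg_usage_error", "P and Q shapes differ")
  }
  field <- .balance_field_for(settings, Q)
  gamma_eff <- settings$gamma
  for (h in seq_len(settings$max_step_shrink + 1L)) {
    trial <- P + field(P, gamma_eff)
    if (min(trial) > settings$positivity_floor) {
      out <- transition_matrix(trial, tol = 1e-9)
      attr(out, "effective_gamma") <- gamma_eff
      return(out)
    }
    gamma_eff <- gamma_eff / 2
  }
  .sg_stop("sg_solver_error",
           "positivity floor unreachable after %d gain halvings (min trial entry %.3g)",
           settings$max_step_shrink, min(trial))
}

#' Evolve a balance-breaking model
#'
#' Runs the chosen variant in the chosen time mode from a strictly positive
#' row-stochastic start. In continuous mode the matrix ODE is integrated
#' with the adaptive projected Runge-Kutta scheme (row sums affinely
#' re-corrected each accepted step, positivity-floor step rejection); in
#' sampled mode [step_sampled()] is iterated. The goal functional of the
#' variant ([entropy_production()] or [kl_from_uniform()]) is recorded at
#' every stored sample, along with the row-sum residual and the minimum
#' entry.
#'
#' These trajectories do not converge: they ascend an objective that is
#' unbounded as entries approach the simplex boundary. Runs end at
#' `t_end`/`n_steps` or when the positivity safeguard stagnates; the
#' `status` field distinguishes the two.
#'
#' @param P0 Starting [transition_matrix()].
#' @param settings A [balance_settings()].
#' @param Q Backward matrix ([backward_matrix()]), required for the
#'   `"backward"` variant, ignored by `"uniform"`. Held fixed throughout.
#' @return An object of class `"balance_trajectory"`: list with `times`
#'   (sample times, or step indices in sampled mode), `matrices` (list of
#'   stored matrices), `goal` (the variant's functional per sample),
#'   `row_sum_residual`, `min_entry`, `effective_gamma` (sampled mode),
#'   `variant`, `mode`, `status`.
#' @examples
#' fix <- detailed_balance_pair(3, seed = 7)
#' pert <- perturb_pair(fix$P, fix$Q, epsilon = 1e-3, seed = 8)
#' traj <- evolve_balance(pert$P, balance_settings(gamma = 0.01, n_steps = 50),
#'                        Q = pert$Q)
#' diff(range(traj$goal)) > 0  # entropy production grew
#' @export
evolve_balance <- function(P0, settings = balance_settings(), Q = NULL) {
  P0 <- .as_positive_matrix(transition_matrix(P0), "transition matrix")
  N <- nrow(P0)
  if (settings$variant == "backward" && is.null(Q)) {
    .sg_stop("sg_usage_error", "the backward variant needs a backward matrix Q")
  }
  goal_fn <- .goal_for(settings, Q)
  if (settings$mode == "sampled") {
    mats <- vector("list", settings$n_steps + 1L)
    eff <- numeric(settings$n_steps + 1L)
    mats[[1]] <- P0
    eff[1] <- NA_real_
    status <- "n_steps"
    P <- P0
    k <- 1L
    for (s in seq_len(settings$n_steps)) {
      stepped <- tryCatch(step_sampled(P, settings, Q),
                          sg_solver_error = function(e) NULL)
      if (is.null(stepped)) {
        status <- "floor_stagnation"
        break
      }
      P <- unclass(stepped)
      k <- k + 1L
      mats[[k]] <- P
      eff[k] <- attr(stepped, "effective_gamma")
    }
    mats <- mats[seq_len(k)]
    eff <- eff[seq_len(k)]
    times <- seq_len(k) - 1
  } else {
    field_m <- .balance_field_for(settings, Q)
    gamma <- settings$gamma
    field <- function(y) {
      P <- matrix(y, N, N)
      as.numeric(field_m(P, gamma))
    }
    project <- function(y) {
      P <- matrix(y, N, N)
      as.numeric(P - (rowSums(P) - 1) / N)
    }
    out <- .sg_integrate(as.numeric(P0), field, t_end = settings$t_end,
                         rtol = settings$rtol, atol = settings$atol,
                         project = project, floor = settings$positivity_floor,
                         max_halvings = settings$max_step_shrink)
    times <- out$times
    mats <- lapply(seq_len(nrow(out$states)),
                   function(i) matrix(out$states[i, ], N, N))
    eff <- rep(NA_real_, length(mats))
    status <- out$status
  }
  structure(list(
    times = times,
    matrices = mats,
    goal = vapply(mats, goal_fn, numeric(1)),
    row_sum_residual = vapply(mats, function(M) max(abs(rowSums(M) - 1)), numeric(1)),
    min_entry = vapply(mats, min, numeric(1)),
    effective_gamma = eff,
    variant = settings$variant, mode = settings$mode,
    status = status, settings = settings
  ), class = "balance_trajectory")
}

#' @export
print.balance_trajectory <- function(x, ...) {
  cat(sprintf("<balance_trajectory> variant: %s, mode: %s, %d samples, status: %s\n",
              x$variant, x$mode, length(x$times), x$status))
  cat(sprintf("  goal %.8g -> %.8g; min entry %.3g; max row-sum residual %.3g\n",
              x$goal[1], x$goal[length(x$goal)], min(x$min_entry),
              max(x$row_sum_residual)))
  invisible(x)
}
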