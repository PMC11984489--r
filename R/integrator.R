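# Internal adaptive Runge-Kutta (Cash-Karp 4/5) with two safeguards that the
# entropy flows need at every accepted step: an affine re-projection onto the
# constraint set (cancels integrator drift exactly) and rejection/halving of
# any trial step whose state would cross the positivity floor. The continuous
# flows repel the boundary analytically, but a discrete step can overshoot.

.CK_A <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(3 / 10, -9 / 10, 6 / 5),
  c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
  c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)
)
.CK_B5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
.CK_B4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

# One Cash-Karp step. Returns list(y5, err) or NULL if a stage left the
# domain of the field (non-finite derivative).
.ck_step <- function(y, h, field) {
  k <- vector("list", 6)
  k[[1]] <- field(y)
  if (any(!is.finite(k[[1]]))) return(NULL)
  for (s in 2:6) {
    a <- .CK_A[[s - 1]]
    incr <- a[1] * k[[1]]
    if (s > 2) for (j in 2:(s - 1)) incr <- incr + a[j] * k[[j]]
    k[[s]] <- field(y + h * incr)
    if (any(!is.finite(k[[s]]))) return(NULL)
  }
  y5 <- y
  y4 <- y
  for (s in 1:6) {
    y5 <- y5 + h * .CK_B5[s] * k[[s]]
    y4 <- y4 + h * .CK_B4[s] * k[[s]]
  }
  list(y5 = y5, err = y5 - y4)
}

# Integrate dy/dt = field(y) from 0 to t_end, storing every accepted step.
#
# project:  function applied to each accepted state (affine drift correction)
# floor:    min component allowed; trial states at or below it are rejected
# stop_fn:  optional function(y) -> TRUE to terminate early ("converged")
# on_sample: optional function(y, t) recording diagnostics per accepted step
#
# Returns list(times, states [matrix, one row per sample], status, n_steps)
# with status one of "t_end", "converged", "floor_stagnation".
.sg_integrate <- function(y0, field, t_end, rtol = 1e-8, atol = 1e-10,
                          project = identity, floor = 1e-12,
                          max_halvings = 40L, stop_fn = NULL,
                          max_steps = 500000L) {
  stopifnot(t_end > 0, rtol > 0, atol > 0)
  y <- project(y0)
  t <- 0
  f0 <- field(y)
  if (any(!is.finite(f0))) {
    stop("vector field is not finite at the initial state", call. = FALSE)
  }
  h <- min(t_end, 0.1 / max(max(abs(f0)), 1e-8))
  # a step this small makes no progress worth recording: the state is
  # pinned at the positivity floor (the balance flows reach it in finite
  # time) and the run is reported as stagnated rather than ground on
  h_min <- t_end * 1e-10
  times <- numeric(0)
  states <- list()
  record <- function(yy, tt) {
    times[[length(times) + 1L]] <<- tt
    states[[length(states) + 1L]] <<- yy
  }
  record(y, t)
  status <- "t_end"
  halvings <- 0L
  steps <- 0L
  if (!is.null(stop_fn) && isTRUE(stop_fn(y))) {
    status <- "converged"
    t <- t_end  # skip the loop
  }
  while (t < t_end) {
    steps <- steps + 1L
    if (steps > max_steps) {
      stop(sprintf("integrator exceeded %d steps without reaching t_end", max_steps),
           call. = FALSE)
    }
    h <- min(h, t_end - t)
    trial <- suppressWarnings(.ck_step(y, h, field))
    reject_floor <- is.null(trial) || min(trial$y5) <= floor
    if (reject_floor) {
      halvings <- halvings + 1L
      if (halvings > max_halvings || h / 2 < h_min) {
        status <- "floor_stagnation"
        break
      }
      h <- h / 2
      next
    }
    err <- max(abs(trial$err) / (atol + rtol * pmax(abs(y), abs(trial$y5))))
    if (err > 1) {
      h <- h * max(0.2, 0.9 * err^(-0.25))
      next
    }
    y_new <- project(trial$y5)
    if (min(y_new) <= floor) {
      halvings <- halvings + 1L
      if (halvings > max_halvings || h / 2 < h_min) {
        status <- "floor_stagnation"
        break
      }
      h <- h / 2
      next
    }
    # accepted
    halvings <- 0L
    t <- t + h
    y <- y_new
    record(y, t)
    if (!is.null(stop_fn) && isTRUE(stop_fn(y))) {
      status <- "converged"
      break
    }
    h <- h * min(5, max(0.2, 0.9 * max(err, 1e-16)^(-0.2)))
  }
  list(times = unlist(times),
       states = do.call(rbind, states),
       status = status,
       n_steps = steps)
}
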