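test_that("the production gradient matches finite differences and log algebra", {
  # at detailed balance every entry is log(1) + 1 = 1
  fix <- detailed_balance_pair(4, seed = 2)
  expect_equal(production_gradient(fix$P, fix$Q), matrix(1, 4, 4),
               tolerance = 1e-12)
  # central finite differences of entropy production entry by entry, N = 3
  P <- unclass(random_stochastic_matrix(3, seed = 10))
  Q <- unclass(random_stochastic_matrix(3, seed = 11))
  G <- production_gradient(P, Q)
  G_fd <- matrix(fd_gradient(function(v) {
    sum(v * (log(v) - log(as.numeric(Q))))
  }, as.numeric(P)), 3, 3)
  expect_lt(max(abs(G - G_fd)) / max(abs(G)), 1e-6)
  # multiplying Q by e^c shifts every gradient entry by exactly -c
  c0 <- 0.3
  expect_equal(production_gradient(P, Q * exp(c0)), G - c0, tolerance = 1e-12)
})

test_that("Lagrange multipliers cancel the row sums of the update", {
  fix <- detailed_balance_pair(3, seed = 6)
  expect_equal(lagrange_multipliers(fix$P, fix$Q), rep(1, 3), tolerance = 1e-12)
  # frozen two-state hand evaluation
  P <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  Q <- rbind(c(0.4, 0.5), c(0.3, 0.5))
  expect_equal(lagrange_multipliers(P, Q),
               c(1.0243950820847160015, 1.2350018146228677768),
               tolerance = 1e-14)
  # defining property on random pairs: rows of (G - lambda) sum to zero
  for (seed in 1:25) {
    N <- 2 + (seed %% 5)
    Pr <- unclass(random_stochastic_matrix(N, seed = seed))
    Qr <- unclass(random_stochastic_matrix(N, seed = seed + 1000))
    resid <- rowSums(production_gradient(Pr, Qr) - lagrange_multipliers(Pr, Qr))
    expect_lt(max(abs(resid)), 1e-12)
  }
})

test_that("the balance-breaking field is the row-centered log-ratio", {
  fix <- detailed_balance_pair(5, seed = 9)
  expect_lt(max(abs(balance_field(fix$P, fix$Q))), 1e-12)
  for (seed in 1:100) {
    N <- 2 + (seed %% 4)
    P <- unclass(random_stochastic_matrix(N, seed = seed))
    Q <- unclass(random_stochastic_matrix(N, seed = seed + 5000))
    gam <- 0.7
    FF <- balance_field(P, Q, gamma = gam)
    expect_lt(max(abs(rowSums(FF))), 1e-12)
    # compositional oracle: gamma * (gradient - multipliers)
    expect_equal(FF,
                 gam * (production_gradient(P, Q) - lagrange_multipliers(P, Q)),
                 tolerance = 1e-12)
  }
})

test_that("the uniform-baseline field is baseline-independent", {
  N <- 4
  expect_lt(max(abs(uniform_field(matrix(1 / N, N, N)))), 1e-12)
  P <- unclass(random_stochastic_matrix(N, seed = 13))
  expect_equal(uniform_field(P, p_star = 1 / N^2), uniform_field(P, p_star = 1),
               tolerance = 1e-12)
  # two-state hand evaluation: row-centered logs give +/- log(9)/2
  P2 <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  F2 <- uniform_field(P2, gamma = 1)
  expect_equal(F2[1, ], c(log(9) / 2, -log(9) / 2), tolerance = 1e-12)
  expect_equal(F2[2, ], c(0, 0), tolerance = 1e-12)
})

test_that("the backward field with constant reference is the uniform field", {
  P <- unclass(random_stochastic_matrix(4, seed = 17))
  Qc <- matrix(1 / 16, 4, 4)
  expect_equal(balance_field(P, Qc, gamma = 2), uniform_field(P, gamma = 2),
               tolerance = 1e-12)
})

test_that("the backward field vanishes exactly when log(P/Q) is row-constant", {
  # parameterized family at N = 2: P rows (a, 1-a); Q rows scaled so the
  # log-ratio is row-constant iff s = 1
  for (a in seq(0.1, 0.9, by = 0.1)) {
    for (s in c(0.5, 1, 2)) {
      P <- rbind(c(a, 1 - a), c(0.5, 0.5))
      Q <- rbind(c(a * 0.8, (1 - a) * 0.8 * s), c(0.5, 0.5))
      FF <- balance_field(P, Q)
      if (s == 1) expect_lt(max(abs(FF)), 1e-12) else expect_gt(max(abs(FF)), 1e-6)
    }
  }
})

test_that("sampled steps preserve rows, respect the floor, and match the map", {
  # equilibrium is a fixed point
  fix <- detailed_balance_pair(3, seed = 21)
  s <- balance_settings(gamma = 0.05, variant = "backward")
  expect_equal(unclass(step_sampled(fix$P, s, fix$Q)), unclass(fix$P),
               tolerance = 1e-12, ignore_attr = TRUE)
  # frozen term-by-term evaluation of one uniform-variant step
  P <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  su <- balance_settings(gamma = 0.05, variant = "uniform")
  expect_equal(unclass(step_sampled(P, su)),
               rbind(c(0.72118244650968009034, 0.27881755349031990966),
                     c(0.38986337229729589045, 0.61013662770270410955)),
               tolerance = 1e-14, ignore_attr = TRUE)
  # row sums preserved on 100 random fixtures
  for (seed in 1:100) {
    N <- 2 + (seed %% 4)
    P0 <- random_stochastic_matrix(N, seed = seed)
    Q0 <- random_stochastic_matrix(N, seed = seed + 7000)
    out <- step_sampled(P0, balance_settings(gamma = 0.01), Q0)
    expect_lt(max(abs(rowSums(unclass(out)) - 1)), 1e-12)
    expect_gt(min(out), 0)
  }
})

test_that("the sampled-step safeguard halves the gain near the boundary", {
  # an entry close to the floor forces transient gain halving
  P <- rbind(c(1e-5, 1 - 1e-5), c(0.5, 0.5))
  su <- balance_settings(gamma = 0.5, variant = "uniform", positivity_floor = 1e-9)
  out <- step_sampled(P, su)
  expect_lt(attr(out, "effective_gamma"), 0.5)
  expect_gt(min(out), 1e-9)
  # unreachable floor: even a fully shrunk step crosses it
  s_bad <- balance_settings(gamma = 0.5, variant = "uniform",
                            positivity_floor = 1e-5, max_step_shrink = 5)
  expect_error(step_sampled(P, s_bad), "floor unreachable")
})

test_that("balanced pairs are constant trajectories; perturbed ones ascend", {
  fix <- detailed_balance_pair(4, seed = 30)
  traj <- evolve_balance(fix$P, balance_settings(gamma = 0.02, n_steps = 50),
                         Q = fix$Q)
  expect_lt(max(abs(unclass(traj$matrices[[51]]) - unclass(fix$P))), 1e-12)
  expect_lt(max(abs(diff(traj$goal))), 1e-12)
  # an epsilon-perturbed start breaks the equilibrium: the entropy
  # production and the balance residual grow monotonically
  pert <- perturb_pair(fix$P, fix$Q, epsilon = 1e-3, seed = 31)
  tr <- evolve_balance(pert$P, balance_settings(gamma = 0.005, n_steps = 100),
                       Q = pert$Q)
  expect_true(all(diff(tr$goal) > 0))
  resid <- vapply(tr$matrices, function(M) balance_residual(M, pert$Q), numeric(1))
  expect_true(all(diff(resid) > 0))
})

test_that("the uniform variant drives matrices toward the boundary until the floor engages", {
  U <- matrix(1 / 4, 4, 4)
  pert <- perturb_pair(U, NULL, epsilon = 1e-3, seed = 41)
  tr <- evolve_balance(pert$P,
                       balance_settings(variant = "uniform", mode = "continuous",
                                        gamma = 1, t_end = 10))
  expect_identical(tr$status, "floor_stagnation")
  expect_true(all(diff(tr$goal) > -1e-10))
  expect_gt(tr$goal[length(tr$goal)], tr$goal[1])
  expect_true(all(tr$row_sum_residual < 1e-10))
  expect_true(all(tr$min_entry > 0))
})

test_that("continuous trajectories are invariant to gamma up to time rescaling", {
  fix <- detailed_balance_pair(3, seed = 50)
  pert <- perturb_pair(fix$P, fix$Q, epsilon = 1e-2, seed = 51)
  end_of <- function(gamma, t_end) {
    tr <- evolve_balance(pert$P,
                         balance_settings(variant = "backward", mode = "continuous",
                                          gamma = gamma, t_end = t_end,
                                          rtol = 1e-10, atol = 1e-12),
                         Q = pert$Q)
    unclass(tr$matrices[[length(tr$matrices)]])
  }
  expect_lt(max(abs(end_of(1, 0.5) - end_of(0.25, 2))), 1e-8)
})

test_that("sampled endpoints converge to the continuous endpoint at first order", {
  fix <- detailed_balance_pair(3, seed = 60)
  pert <- perturb_pair(fix$P, fix$Q, epsilon = 5e-2, seed = 61)
  t_end <- 0.5
  cont <- evolve_balance(pert$P,
                         balance_settings(variant = "backward", mode = "continuous",
                                          gamma = 1, t_end = t_end,
                                          rtol = 1e-11, atol = 1e-13),
                         Q = pert$Q)
  ref <- unclass(cont$matrices[[length(cont$matrices)]])
  errs <- sapply(c(0.1, 0.01, 0.001), function(g) {
    tr <- evolve_balance(pert$P,
                         balance_settings(variant = "backward", mode = "sampled",
                                          gamma = g, n_steps = round(t_end / g)),
                         Q = pert$Q)
    max(abs(unclass(tr$matrices[[length(tr$matrices)]]) - ref))
  })
  expect_true(all(diff(errs) < 0))
  # first-order rate: error ratio tracks the step-size ratio
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("every stored matrix in every trajectory is row-stochastic and positive", {
  for (seed in 1:10) {
    N <- 2 + (seed %% 4)
    fix <- detailed_balance_pair(N, seed = seed + 70)
    pert <- perturb_pair(fix$P, fix$Q, epsilon = 1e-3, seed = seed + 170)
    for (mode in c("sampled", "continuous")) {
      for (variant in c("backward", "uniform")) {
        tr <- evolve_balance(pert$P,
                             balance_settings(variant = variant, mode = mode,
                                              gamma = 0.01, n_steps = 30,
                                              t_end = 0.3),
                             Q = pert$Q)
        expect_true(all(tr$row_sum_residual < 1e-10))
        expect_true(all(tr$min_entry > 0))
      }
    }
  }
})
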