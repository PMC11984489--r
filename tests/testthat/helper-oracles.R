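# Independent numerical oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# central finite differences of a scalar function of a vector/matrix
fd_gradient <- function(f, x, h = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

# null-space-basis construction of the orthogonal projector onto {u: Au=0}
nullspace_projector <- function(A) {
  s <- svd(A, nu = 0, nv = ncol(A))
  r <- sum(s$d > 1e-12 * max(s$d))
  V0 <- s$v[, seq(r + 1, ncol(A)), drop = FALSE]
  V0 %*% t(V0)
}

# equality-constrained QP oracle: argmin ||x - p||^2 s.t. A x = b, via the
# KKT system [I A^T; A 0] [x; mu] = [p; b]
qp_project <- function(p, A, b) {
  n <- length(p)
  m <- nrow(A)
  KKT <- rbind(cbind(diag(n), t(A)), cbind(A, matrix(0, m, m)))
  sol <- solve(KKT, c(p, b))
  sol[seq_len(n)]
}

# 1-D dual root solve for the single-moment (mean-position) Gibbs problem:
# find lambda with sum(q * softmax(lambda * q)) = M
gibbs_lambda_1d <- function(q, M, interval = c(-50, 50)) {
  gap <- function(l) {
    w <- exp(l * q - max(l * q))
    sum(q * w) / sum(w) - M
  }
  stats::uniroot(gap, interval, tol = 1e-14)$root
}

# log-log least-squares slope
loglog_slope <- function(x, y) {
  stats::coef(stats::lm(log(y) ~ log(x)))[[2]]
}
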