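---
title: "Speed-gradient entropy dynamics: models, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-gradient entropy dynamics: models, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgentropy)
```

## The models

### Entropy ascent on the simplex

A discrete system with states $1,\dots,n$ and occupation probabilities
$p_i$ carries information entropy $S(p) = -K \sum_i p_i \ln p_i$, with $K$
a positive scale constant (the Boltzmann constant in the physical
reading; $K = 1$, plain nats, by default). The maximum-entropy principle
selects, among all distributions satisfying known linear constraints
$A p = b$, the one maximizing $S$ — the Gibbs distribution
$p_i \propto \exp\big((A^\top\lambda)_i\big)$. The speed-gradient
principle turns this variational statement into dynamics: the state moves
along the constraint-compatible direction in which $S$ grows fastest,

$$
\frac{dp}{dt} \;=\; \gamma\, P_A\, \nabla S(p), \qquad
P_A = I_n - A^\top (A A^\top)^{-1} A ,
$$

where $P_A$ is the orthogonal projector onto $\{u : A u = 0\}$ and
$\gamma > 0$ a gain. Three structural facts drive everything the package
tests:

* **Lyapunov identity.** $\dot S = \nabla S^\top u = \gamma \lVert P_A
  \nabla S \rVert^2 \ge 0$: entropy is nondecreasing, strictly until the
  projected gradient vanishes — which happens exactly at the constrained
  maximizer, by convexity unique.
* **Conservation.** $A \dot p = 0$, so $A p = b$ holds for all time if it
  holds initially; with the normalization row folded into $A$, total mass
  is conserved by the same mechanism.
* **Positivity.** $\partial S / \partial p_i = -K(\ln p_i + 1)$ diverges
  as $p_i \to 0$, so the exact flow repels the simplex boundary and never
  leaves the interior it starts in.

A note on signs: one can find the flow written with the field
$\gamma P_A (\ln p + 1)$, i.e. without the $-K$ of the true gradient of
$S$. That field *descends* the entropy. Since the model's purpose is
maximum entropy growth, `sgentropy` uses the true gradient by default and
keeps the other sign available as `literal_eq9 = TRUE` for comparison.
$K$ multiplies the gradient, so it is observationally equivalent to a
gain rescaling; we keep it as a separate parameter defaulting to 1.

### Detailed-balance breaking on transition matrices

For a system hopping among $N$ coarse-grained states with forward
transition probabilities $P_{ij}$ (rows summing to 1) and backward
probabilities $P_{ji}$, the entropy production

$$
\dot S = \sum_{i,j} P_{ij} \log \frac{P_{ij}}{P_{ji}}
$$

is a Kullback–Leibler-type divergence between forward and time-reversed
transition statistics. It is zero iff $P_{ij} = P_{ji}$ (detailed
balance) and otherwise measures how far the system is from equilibrium;
in whole-brain imaging its magnitude tracks physical and cognitive load.
Modelling a system that *strives to break* balance as fast as possible,
the speed-gradient ascent of $\dot S$ in the forward entries — with the
backward matrix frozen and row normalization enforced through per-row
Lagrange multipliers $\lambda_i = 1 + \frac1N \sum_l \log(P_{il}/P_{li})$
— gives the row-centered log-ratio field

$$
\dot P_{ij} = \gamma \Big[ \log\frac{P_{ij}}{P_{ji}}
  - \frac1N \sum_l \log\frac{P_{il}}{P_{li}} \Big],
$$

its sampled-time analogue $P(t) = P(t-1) + \text{field}(P(t-1))$, and a
second variant in which the reference is not the backward matrix but the
uniform joint baseline $P^* = 1/N^2$. Structure mirrored in tests:

* rows of the field sum to zero identically, so row-stochasticity is
  conserved;
* the field vanishes exactly at detailed balance (backward variant) or on
  uniform-row matrices (uniform variant) — but these equilibria are
  *unstable*: the goal functional is at a minimum there, and any
  admissible perturbation grows;
* with a constant reference $Q_{ij} \equiv P^*$ the backward field
  reduces algebraically to the uniform field, and the value of $P^*$
  cancels from the dynamics entirely (only the *metric* depends on it);
* unlike the simplex flow, these trajectories do not converge: they
  ascend an objective unbounded on the boundary, so runs end at the
  horizon or when the positivity safeguard stagnates.

## Interpretive choices

Three points are ambiguous in the usual presentation of these models and
had to be fixed:

* **Joint vs conditional.** $P_{ij}$ is sometimes introduced as the
  probability of the joint event $\{x_{t-1}=i, x_t=j\}$, yet normalized
  row-wise as a conditional transition matrix. The package follows the
  row-stochastic reading, which the normalization constraint makes
  self-consistent; under the joint reading the functional and fields are
  unchanged, only the container invariant would differ.
* **Frozen backward matrix.** The backward probabilities are treated as a
  fixed parameter matrix, not as the live transpose of the evolving $P$
  (which would couple the entries and change the gradient). The
  `backward_matrix` container stores them index-matched — `Q[i, j]`
  holds the reverse probability of the $i \to j$ step — so the objective
  is an elementwise ratio and no silent transpose can occur.
* **Baseline convention.** `kl_from_uniform()` defaults to the joint
  baseline $1/N^2$ and exposes `reference = "row"` ($1/N$); the two
  differ by exactly $N \log N$ and generate identical dynamics.

"Detailed balance" here means the elementwise condition
$P_{ij} = P_{ji}$, not stationary-distribution-weighted reversibility
$\pi_i P_{ij} = \pi_j P_{ji}$; the symmetric-matrix fixtures instantiate
the former.

## Numerical design

**Integrator.** Both continuous models use one adaptive embedded
Runge–Kutta scheme (Cash–Karp 4(5), written for this package) with two
safeguards applied at every accepted step:

1. *affine re-projection* $p \leftarrow p - A^\top (A A^\top)^{-1}(A p -
   b)$ (for matrices, the per-row equivalent $P_{ij} \leftarrow P_{ij} -
   (\text{rowsum}-1)/N$), which cancels constraint drift exactly instead
   of letting it accumulate at the local-error rate;
2. *positivity-floor rejection*: a trial step taking any component to or
   below `positivity_floor` ($10^{-12}$) is rejected and retried at half
   the step. The exact flows repel the boundary, but a discrete step can
   overshoot.

A run is declared **floor-stagnated** when the safeguard halves the step
more than `max_step_shrink` (40) consecutive times *or* the step falls
below $10^{-10} \, t_{\mathrm{end}}$. The second clause matters for the
balance models: their min entry reaches the floor in finite time, and
each micro-step before it resets a pure rejection counter, so a
step-size criterion is needed for termination. The same settings govern
the sampled-time maps, where the safeguard transiently halves the
*gain* for the offending step and records the effective value used.

**Stopping.** The simplex flow stops when $\lVert P_A \nabla S
\rVert_2 <$ `convergence_tol` ($10^{-8}$). The local error tolerance
bounds the per-step noise injected into the state, and that noise is
amplified by $1/p_i$ in the gradient; with `atol` $= 10^{-10}$ the
projected-gradient norm reliably reaches $10^{-8}$, and tightening the
tolerances (as the exponential-family recovery test does) pushes it to
$10^{-10}$.

**Rank and feasibility.** The constraint matrix must have full row rank:
it is rejected when the smallest singular value of $A A^\top$ is below
$10^{-10}$ times the largest. The all-ones row is appended unless the
ones direction already lies in the row space, in which case the implied
value of $\sum p_i$ is checked against 1. The generator caps the number
of extra constraints at $n - 2$ so that after augmentation at least one
degree of freedom remains.

**Oracle.** Convergence is judged against `maxent_oracle()`, a damped
Newton iteration on the smooth convex dual
$d(\lambda) = \sum_i e^{(A^\top\lambda)_i - 1} - b^\top \lambda$ with
Hessian $A \,\mathrm{diag}(p)\, A^\top$. It shares no code with the flow;
the test suite additionally cross-checks it on the one-moment instance
against a scalar `uniroot` solve, the projector against an SVD null-space
basis, and the affine projection against a KKT quadratic-programming
solve.

## Synthetic fixtures

All inputs are generated, seeded and bit-reproducible (generators save
and restore the caller's RNG state):

* interior simplex points: flat Dirichlet mixed with a $10^{-3}$ floor,
  exchangeable across coordinates;
* constraint sets: Gaussian rows with $b := A p_f$ for a generated
  interior $p_f$, so interior feasibility holds by construction;
* row-stochastic matrices: Dirichlet rows with an entry floor;
* detailed-balance pairs: a random symmetric matrix driven to doubly
  stochastic by symmetric Sinkhorn scaling, then symmetrized — giving a
  symmetric row-stochastic $P$ with $Q = P^\top$ and entropy production
  zero to rounding;
* perturbations: zero-row-sum, infinity-norm $\varepsilon$, applied to
  $P$ only. Zero row sums avoid renormalization, which would entangle
  entries and spoil the clean $O(\varepsilon^2)$ curvature of the KL
  functional at its minimum (verified as a log–log slope of $2 \pm 0.1$
  over $\varepsilon \in \{10^{-1},\dots,10^{-4}\}$).

Tests run at desk scale, $n \le 10$ states and $m \le 4$ constraints for
the simplex flow and $N \in \{2,\dots,8\}$ for the matrix models, with
$N = 100$ — the coarse-grained connectome scale — exercised in the
generator's timing check. The fixtures emulate the *mathematical*
setting only: probabilities are exact, matrices exactly stochastic, and
perturbations designed. They do not emulate empirical brain data —
estimation noise in transition matrices, non-Markov memory, zero
(unobserved) transitions, or any fitting of $\gamma$ to recordings — so
green tests certify the dynamics' stated properties, not fidelity to any
recorded brain.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | 1 (flow), 0.01 (maps) | gain; pure time rescaling in continuous models, step size in sampled maps |
| `K` | 1 | entropy scale (nats); multiplies the gradient |
| `convergence_tol` | $10^{-8}$ | projected-gradient norm at which the simplex flow reports convergence |
| `rtol`, `atol` | $10^{-8}$, $10^{-10}$ | integrator local-error control |
| `positivity_floor` | $10^{-12}$ | rejection threshold for boundary overshoot |
| `max_step_shrink` | 40 | halvings before stagnation is declared |
| `epsilon` | $10^{-3}$ | perturbation scale used for instability runs |

Sampled-map gains: the default 0.01 keeps the first-order map within the
region where each step strictly increases the goal; the convergence of
sampled endpoints to the continuous endpoint is first-order in $\gamma$
(checked at $\gamma \in \{0.1, 0.01, 0.001\}$).

## Known limitations

* Linear equality constraints only; no inequalities, time-varying
  right-hand sides, or network-topology-aware projections.
* The balance models' ascent is taken as given — the package simulates
  the hypothesized law; it does not test it against empirical state
  sequences, estimate transition matrices from data, or choose between
  the backward and uniform variants.
* The sampled maps are first-order and can cross the boundary for large
  gains; the safeguard then deviates from the printed map by transiently
  reducing the gain (and says so in the trajectory's
  `effective_gamma`).
* Differential (continuous-state) entropy is out of scope.
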