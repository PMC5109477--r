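# Synthetic fluctuation generators with known statistical structure.
#
# Two families: (i) i.i.d. Gaussian ensembles with a prescribed per-component
# site covariance S (so <dR_i . dR_j> = 3 S_ij exactly in expectation), the
# substrate of the stiffness and correlation estimators; (ii) coupled
# Ornstein-Uhlenbeck networks dX = -A X dt + B dW integrated per spatial
# component, whose stationary and lagged covariances have closed forms
# (Lyapunov equation / matrix exponential), giving ground truth for the
# time-delayed estimators and the causality scan.

synthetic_labels <- function(n_sites) {
  make_site_labels(seq_len(n_sites), "SYN", "CA", "A")
}

#' Gaussian ensemble specification
#'
#' @param n_sites number of sites.
#' @param S per-component site covariance matrix (A^2), symmetric positive
#'   semi-definite. The 3-D dot covariance is `3 * S_ij`.
#' @param n_frames frames to draw (i.i.d.).
#' @param seed mandatory RNG seed.
#' @param dt nominal frame spacing, ps (frames are independent; default 1).
#' @return Object of class `"gaussian_ensemble_spec"`.
#' @export
gaussian_ensemble_spec <- function(n_sites, S, n_frames, seed, dt = 1) {
  S <- as.matrix(S)
  if (nrow(S) != n_sites || ncol(S) != n_sites)
    abort_spec("S must be n_sites x n_sites")
  if (max(abs(S - t(S))) > 1e-12 * max(abs(S), 1))
    abort_spec("S must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    abort_spec(sprintf("S is not positive semi-definite (eigenvalue %.3g)", min(ev)))
  if (missing(seed) || is.null(seed)) abort_spec("seed is mandatory")
  if (n_frames < 2) abort_spec("n_frames must be >= 2")
  structure(list(n_sites = n_sites, S = S, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), dt = dt),
            class = "gaussian_ensemble_spec")
}

#' Sample an i.i.d. Gaussian fluctuation ensemble
#'
#' Each spatial component of each frame is an independent draw from
#' N(0, S); the output is mean-centered (sample means removed) so it
#' satisfies the fluctuation-series invariant exactly. Deterministic under
#' the spec's seed.
#'
#' @param spec a [gaussian_ensemble_spec()].
#' @return A [fluctuation_series()].
#' @export
sample_gaussian_ensemble <- function(spec) {
  stopifnot(inherits(spec, "gaussian_ensemble_spec"))
  e <- eigen(spec$S, symmetric = TRUE)
  Shalf <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  deltas <- withr::with_seed(spec$seed, {
    arr <- array(NA_real_, c(spec$n_frames, spec$n_sites, 3))
    for (c in 1:3) {
      Z <- matrix(stats::rnorm(spec$n_frames * spec$n_sites), spec$n_frames)
      arr[, , c] <- Z %*% Shalf
    }
    arr
  })
  means <- apply(deltas, c(2, 3), mean)
  deltas <- sweep(deltas, c(2, 3), means)
  fluctuation_series(deltas, matrix(0, spec$n_sites, 3), spec$dt,
                     synthetic_labels(spec$n_sites),
                     source = sprintf("gaussian_ensemble(seed=%d)", spec$seed))
}

#' Ornstein-Uhlenbeck network specification
#'
#' Defines the linear stochastic network dX = -A X dt + B dW (per spatial
#' component). Stationarity requires every eigenvalue of `A` to have
#' positive real part; discretization fidelity of the Euler-Maruyama
#' integrator requires `dt <= 0.1 / max |eigenvalue(A)|`.
#'
#' @param A drift (site-coupling) matrix, 1/ps.
#' @param B noise amplitude matrix, A/sqrt(ps).
#' @param dt integration / output time step, ps.
#' @param n_steps stored steps.
#' @param seed mandatory RNG seed.
#' @param ground_truth_edges optional data.frame (driver, follower).
#' @return Object of class `"ou_network_spec"`.
#' @export
ou_network_spec <- function(A, B, dt, n_steps, seed, ground_truth_edges = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != ncol(A) || any(dim(B) != dim(A)))
    abort_spec("A and B must be square matrices of equal size")
  ev <- eigen(A, only.values = TRUE)$values
  if (min(Re(ev)) <= 0)
    abort_spec(sprintf("A is not stable: eigenvalue with Re = %.3g <= 0", min(Re(ev))))
  bound <- 0.1 / max(Mod(ev))
  if (dt > bound + 1e-12)
    abort_spec(sprintf("dt = %g ps exceeds the discretization bound 0.1/max|eig(A)| = %g ps",
                       dt, bound))
  if (missing(seed) || is.null(seed)) abort_spec("seed is mandatory")
  structure(list(n_sites = nrow(A), A = A, B = B, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 ground_truth_edges = ground_truth_edges,
                 min_rate = min(Re(ev))),
            class = "ou_network_spec")
}

#' Simulate a coupled Ornstein-Uhlenbeck network
#'
#' Euler-Maruyama integration, independent per spatial component, starting
#' at the origin; a burn-in of 10 relaxation times (10 / min Re eigenvalue)
#' is integrated and discarded so the stored steps are (approximately)
#' stationary. The stored series is mean-centered. Deterministic under the
#' spec's seed.
#'
#' @param spec an [ou_network_spec()].
#' @return A [fluctuation_series()] with `dt = spec$dt`.
#' @export
simulate_ou_network <- function(spec) {
  stopifnot(inherits(spec, "ou_network_spec"))
  n_burn <- as.integer(ceiling(10 / (spec$min_rate * spec$dt)))
  raw <- withr::with_seed(spec$seed,
    ou_simulate_cpp(spec$A, spec$B, spec$dt, spec$n_steps, n_burn))
  deltas <- array(raw, c(spec$n_steps, spec$n_sites, 3))
  means <- apply(deltas, c(2, 3), mean)
  deltas <- sweep(deltas, c(2, 3), means)
  fluctuation_series(deltas, matrix(0, spec$n_sites, 3), spec$dt,
                     synthetic_labels(spec$n_sites),
                     source = sprintf("ou_network(seed=%d)", spec$seed))
}

#' Analytic stationary and lagged covariance of an OU network
#'
#' The stationary per-component covariance S solves the Lyapunov equation
#' `A S + S A' = B B'`; the lagged covariance is
#' `M(lag) = expm(-A lag) S`, with `M[j, i] = Cov(x_j(t + lag), x_i(t))`.
#' The 3-D dot-product correlation of the estimators is `3 * M[j, i]` for
#' the ordered pair (i -> j).
#'
#' @param A stable drift matrix (1/ps).
#' @param B noise amplitude matrix.
#' @param lag lag in ps (0 returns S itself).
#' @return Site covariance matrix at the requested lag (A^2 per component).
#' @export
analytic_lagged_covariance <- function(A, B, lag = 0) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  ev <- eigen(A, only.values = TRUE)$values
  if (min(Re(ev)) <= 0) abort_spec("A must be stable (all Re(eig) > 0)")
  Q <- B %*% t(B)
  lhs <- diag(n) %x% A + A %x% diag(n)       # vec(A S + S A') = lhs vec(S)
  S <- matrix(solve(lhs, as.vector(Q)), n, n)
  S <- (S + t(S)) / 2
  resid <- max(abs(A %*% S + S %*% t(A) - Q))
  if (resid > 1e-10 * max(abs(Q), 1))
    abort_spec("Lyapunov system is (near-)singular; cannot solve for the stationary covariance")
  if (lag == 0) return(S)
  as.matrix(Matrix::expm(-A * lag)) %*% S
}

#' Driver-follower chain generator with ground truth
#'
#' Builds a linear OU chain in which site k unidirectionally drives site
#' k + 1: `A = relax * I` with `-coupling` on the first subdiagonal, unit
#' isotropic noise. Returns the simulated fluctuation series together with
#' the ground-truth edge list \{k -> k+1\}.
#'
#' @param n_sites chain length (>= 2).
#' @param coupling coupling rate, 1/ps; must be below `relax` for a
#'   well-separated causal ordering.
#' @param relax per-site relaxation rate, 1/ps.
#' @param dt integration step, ps (must satisfy the OU spec bound).
#' @param n_steps stored steps.
#' @param seed mandatory RNG seed.
#' @return List with `fluct` (a [fluctuation_series()]), `edges`
#'   (data.frame driver/follower) and `spec`.
#' @export
make_driver_follower_chain <- function(n_sites, coupling = 0.5, relax = 1,
                                       dt = 0.05, n_steps = 1e5, seed) {
  if (n_sites < 2) abort_spec("chain needs at least 2 sites")
  if (coupling >= relax)
    abort_spec("coupling must be below relax for a stable, ordered chain")
  A <- diag(relax, n_sites)
  for (k in seq_len(n_sites - 1)) A[k + 1, k] <- -coupling
  spec <- ou_network_spec(A, diag(n_sites), dt, n_steps, seed,
                          ground_truth_edges = data.frame(
                            driver = seq_len(n_sites - 1),
                            follower = seq_len(n_sites - 1) + 1L))
  list(fluct = simulate_ou_network(spec), edges = spec$ground_truth_edges,
       spec = spec)
}

#' Brute-force lagged correlation (reference oracle)
#'
#' Explicit loop over frames and components computing
#' `mean_t dR_i(t) . dR_j(t + lag)` with no vectorized shortcuts. Reference
#' semantics for testing the direct estimator; use only on small inputs.
#'
#' @param fluct a [fluctuation_series()].
#' @param i,j site indices.
#' @param lag_frames non-negative frame offset (< frames).
#' @return Raw lagged dot correlation (A^2).
#' @export
brute_force_lagged_correlation <- function(fluct, i, j, lag_frames) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  nf <- n_frames(fluct)
  if (lag_frames < 0 || lag_frames >= nf)
    abort_argument("lag_frames must be in [0, frames)")
  total <- 0
  count <- 0
  for (t in seq_len(nf - lag_frames)) {
    acc <- 0
    for (c in 1:3) {
      acc <- acc + fluct$deltas[t, i, c] * fluct$deltas[t + lag_frames, j, c]
    }
    total <- total + acc
    count <- count + 1
  }
  total / count
}
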