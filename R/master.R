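# Exact master-equation oracle for short chains.
#
# For n_units <= 3 the joint state space (24^n) is small enough to build the
# full generator of the coupled chain and solve for its stationary
# distribution directly. This provides an independent, deterministic
# reference for the stochastic ensemble simulator.

# Build the (sparse) generator matrix Q over joint states of an n-unit
# chain. Joint state index = 1 + sum_i (s_i - 1) * 24^(i-1), unit 1 leftmost.
# Chain ends have a single neighbor (non-periodic) unless periodic = TRUE.
chain_generator <- function(params, ca, n_units, periodic = FALSE) {
  if (n_units > 3L) stop("n_units must be <= 3 for the exact oracle ",
                         "(24^n joint states)")
  if (n_units < 1L) stop("n_units must be >= 1")
  n_states <- 24L^n_units
  base <- 24L^(seq_len(n_units) - 1L)

  # per-unit transition tables for each (state, left tpm, right tpm) combo
  # are evaluated lazily through unit_transitions(); n <= 3 keeps this cheap.
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  comb <- as.matrix(expand.grid(rep(list(1:24), n_units),
                                KEEP.OUT.ATTRS = FALSE))
  joint_idx <- as.integer(1L + (comb - 1L) %*% base)
  tpm_x <- matrix(state_tpm_x(comb), nrow = nrow(comb))

  for (u in seq_len(n_units)) {
    if (periodic && n_units > 1L) {
      li <- if (u == 1L) n_units else u - 1L
      ri <- if (u == n_units) 1L else u + 1L
      lx <- tpm_x[, li]; rx <- tpm_x[, ri]
    } else {
      lx <- if (u > 1L) tpm_x[, u - 1L] else rep(NA_integer_, nrow(comb))
      rx <- if (u < n_units) tpm_x[, u + 1L] else rep(NA_integer_, nrow(comb))
    }
    for (k in seq_len(nrow(comb))) {
      tr <- unit_transitions(comb[k, u], params, ca, lx[k], rx[k])
      keep <- tr$rate > 0
      if (!any(keep)) next
      to_joint <- joint_idx[k] + (tr$to[keep] - comb[k, u]) * base[u]
      ii <- c(ii, rep(joint_idx[k], sum(keep)))
      jj <- c(jj, as.integer(to_joint))
      xx <- c(xx, tr$rate[keep])
    }
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n_states, n_states))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  Q
}

# Stationary distribution of a generator Q (pi Q = 0, sum(pi) = 1)
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  A <- Matrix::t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi <- as.numeric(Matrix::solve(A, b))
  pi[abs(pi) < 1e-15] <- 0
  pi / sum(pi)
}

#' Exact steady-state activation of a short chain
#'
#' Builds the full master-equation generator over the joint states of an
#' `n_units`-long chain (24^n joint states, so `n_units` must be at most 3),
#' solves for the stationary distribution, and returns the expected fraction
#' of units with tropomyosin in the M (myosin-bound) state -- the model's
#' force proxy. Deterministic; serves as the independent oracle for
#' [simulate_ensemble()].
#'
#' @param params a [param_set()]; its `n_units` field is ignored here.
#' @param ca calcium concentration in micromolar.
#' @param n_units chain length, 1..3.
#' @param periodic couple the two chain ends to each other (default `FALSE`:
#'   end units have one neighbor).
#' @param full return the full stationary distribution and per-unit marginals
#'   alongside the force.
#' @return The expected M-state fraction (scalar), or if `full = TRUE` a list
#'   with elements `force`, `pi` (joint stationary distribution) and
#'   `marginal` (24 x n_units matrix of per-unit state probabilities).
#' @examples
#' p <- thinfil_params("set1")
#' master_equation_force(p, ca = 10, n_units = 1)
#' @export
master_equation_force <- function(params, ca, n_units = 1L,
                                  periodic = FALSE, full = FALSE) {
  stopifnot(inherits(params, "tf_params"))
  if (!is.finite(ca) || ca < 0) stop("ca must be a finite value >= 0")
  n_units <- as.integer(n_units)
  Q <- chain_generator(params, ca, n_units, periodic)
  pi <- stationary_distribution(Q)

  comb <- as.matrix(expand.grid(rep(list(1:24), n_units),
                                KEEP.OUT.ATTRS = FALSE))
  m_frac <- rowMeans(matrix(state_tpm_x(comb) == 2L, nrow = nrow(comb)))
  force <- sum(pi * m_frac)
  if (!full) return(force)
  marg <- vapply(seq_len(n_units), function(u)
    vapply(1:24, function(s) sum(pi[comb[, u] == s]), numeric(1)),
    numeric(24))
  list(force = force, pi = pi, marginal = marg)
}
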