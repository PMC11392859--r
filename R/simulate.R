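#' Simulate an ensemble of stochastic filament trajectories
#'
#' Runs `n_traj` statistically independent continuous-time Markov
#' trajectories of the coupled regulatory-unit chain with an exact
#' event-driven algorithm, and averages them into a force trace. Force is
#' the fraction of units with tropomyosin in the M (myosin-bound) state.
#' Calcium may be constant or an arbitrary waveform; waveforms are
#' discretized to a piecewise-constant grid of width `ca_dt` (exact within
#' each segment by memorylessness of the process).
#'
#' Each trajectory draws from its own deterministic random stream derived
#' from `seed` (stream `i` is seeded from `seed` and the 1-based trajectory
#' index via a splitmix64 hash), so results are bit-identical for identical
#' inputs and independent of trajectory ordering.
#'
#' @param params a [param_set()]; `params$n_units` sets the chain length.
#' @param ca calcium in micromolar: a single number (constant) or a function
#'   of time in seconds returning micromolar.
#' @param duration simulated time after time 0, seconds.
#' @param sample_dt recording interval, seconds.
#' @param n_traj number of trajectories (paper-scale default 1920).
#' @param seed integer master seed.
#' @param burn_in seconds simulated before time 0 (at `ca(t)` for `t < 0`,
#'   or the constant `ca`) to let the chain relax from the all-resting
#'   initial condition (every unit starts with no calcium, switch peptide
#'   off, inhibitory peptide on, tropomyosin blocked).
#' @param record_from time at which recording starts (default 0; may be
#'   negative, e.g. to capture a pre-stimulus baseline inside the burn-in).
#' @param window optional `c(t0, t1)`: additionally accumulate each
#'   trajectory's exact time-averaged M fraction over this window
#'   (`$window_means`), used for steady-state force estimates.
#' @param record_occupancy record the 24 per-state mean occupancy fractions
#'   at every sample time.
#' @param ca_dt discretization step for calcium waveforms, seconds.
#' @param periodic couple the chain ends to each other (default open ends).
#' @return An object of class `tf_trace`: list with `time`, `force`, `se`
#'   (per-time standard error of the ensemble mean), `occupancy` (matrix,
#'   times x 24, if recorded), `window_means`, `n_traj`, `seed`, `n_events`.
#' @seealso [master_equation_force()] for the exact short-chain oracle.
#' @export
simulate_ensemble <- function(params, ca, duration, sample_dt = 0.001,
                              n_traj = 1920L, seed = 1L, burn_in = 0,
                              record_from = 0, window = NULL,
                              record_occupancy = TRUE, ca_dt = 0.001,
                              periodic = FALSE) {
  stopifnot(inherits(params, "tf_params"))
  validate_params(params)
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  n_traj <- as.integer(n_traj)
  if (n_traj < 1L) stop("n_traj must be >= 1")
  if (burn_in < 0) stop("burn_in must be >= 0")
  if (record_from < -burn_in) stop("record_from precedes the burn-in start")

  t_start <- -burn_in
  if (is.function(ca)) {
    edges <- seq(t_start, duration, by = ca_dt)
    if (edges[length(edges)] < duration) edges <- c(edges, duration)
    mid <- (edges[-length(edges)] + edges[-1]) / 2
    vals <- vapply(mid, ca, numeric(1))
    if (any(!is.finite(vals) | vals < 0))
      stop("ca function must return finite values >= 0")
    # collapse runs of equal values to keep the segment list short
    keep <- c(TRUE, diff(vals) != 0)
    ca_times <- edges[-length(edges)][keep]
    ca_values <- vals[keep]
  } else {
    if (!is.finite(ca) || ca < 0) stop("ca must be a finite value >= 0")
    ca_times <- t_start
    ca_values <- ca
  }

  if (is.null(window)) {
    w0 <- 0; w1 <- -1
  } else {
    stopifnot(length(window) == 2L, window[2] > window[1])
    w0 <- window[1]; w1 <- window[2]
  }

  seed <- as.integer(seed)
  res <- cpp_sim_chain(unlist_params(params), params$n_units, periodic,
                       ca_times, ca_values, duration, record_from, sample_dt,
                       w0, w1, n_traj, record_occupancy,
                       0, as.double(seed %% .Machine$integer.max),
                       ru_state(0, 0, 1, "B") - 1L)
  structure(list(
    time = res$time,
    force = res$force,
    se = sqrt(res$force_var / n_traj),
    occupancy = res$occupancy,
    window_means = if (!is.null(window)) res$window_means else NULL,
    n_traj = n_traj, seed = seed, n_events = res$n_events,
    sample_dt = sample_dt), class = "tf_trace")
}

unlist_params <- function(p) {
  c(kCa_plus = p$kCa_plus, kCa_minus = p$kCa_minus,
    kSP_plus = p$kSP_plus, kSP_minus = p$kSP_minus,
    kIP_plus = p$kIP_plus, kIP_minus = p$kIP_minus,
    kMD_plus = p$kMD_plus, kMD_minus = p$kMD_minus,
    kref_BC = p$kref_BC, K_BC = p$K_BC, f_XY = p$f_XY,
    delta = p$delta, lam = p$lam, eta = p$eta, mu = p$mu,
    g_rt = p$gamma / p$rt)
}

#' @export
print.tf_trace <- function(x, ...) {
  cat("Ensemble force trace: ", length(x$time), " samples, t = [",
      format(min(x$time)), ", ", format(max(x$time)), "] s, ",
      x$n_traj, " trajectories (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  peak force %.4f, final force %.4f\n",
              max(x$force), x$force[length(x$force)]))
  invisible(x)
}

#' @export
as.data.frame.tf_trace <- function(x, ...) {
  data.frame(time = x$time, force = x$force, se = x$se)
}
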