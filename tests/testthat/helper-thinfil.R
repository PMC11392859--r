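# Shared fixtures for the test suite. Simulation-based tests use short
# chains, short records and reduced trajectory counts; the statistical
# tolerances are widened accordingly (3 standard errors unless stated).

set1 <- thinfil_params("set1")
set2 <- thinfil_params("set2")

# a short-chain copy for cheap stochastic runs
short_params <- function(p, n_units = 2L) {
  p$n_units <- as.integer(n_units)
  p
}

# steady-state force and Monte-Carlo SE from a short constant-Ca run
ss_force <- function(p, ca, n_traj = 400L, seed = 1L, duration = 1.5) {
  tr <- simulate_ensemble(p, ca, duration = duration, n_traj = n_traj,
                          seed = seed, window = c(duration / 2, duration),
                          record_occupancy = FALSE)
  list(force = mean(tr$window_means),
       se = stats::sd(tr$window_means) / sqrt(n_traj))
}

# all 24 state indices
ALL_STATES <- seq_len(24L)

# Expression sweep used by the twitch-phenotype acceptance checks, at a
# trajectory count where the claimed relaxation effects would be resolved
# if present (Monte-Carlo error on RT50 percent changes is a few points).
# Cached so both checks share one computation.
acceptance_sweep <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- expression_sweep(set2, mutation_spec(0.5, 0.74, 1),
                                 expressions = seq(0, 1, by = 0.1),
                                 n_traj = 1024L, n_repeats = 2L, seed = 29)
    cache
  }
})
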