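# Synthetic-data generators emulating the statistical structure of the two
# wet-lab assays the analysis consumes: in vitro motility velocity-pCa
# point sets and engineered-heart-tissue isometric twitch traces. Noise is
# additive i.i.d. Gaussian in both cases.

#' Generate a synthetic velocity-pCa point set
#'
#' Evaluates a Hill curve `v_max / (1 + 10^(n_h * (pca - pca50)))` on a pCa
#' grid and adds i.i.d. Gaussian noise -- the structure of an in vitro
#' motility assay's sliding-velocity measurements. Deterministic given
#' `seed`.
#'
#' @param v_max,pca50,n_h generating Hill parameters (defaults emulate a
#'   regulated-actin motility curve: half-activation at pCa 6, cooperativity
#'   around 3).
#' @param noise_sd additive Gaussian standard deviation (same units as
#'   `v_max`).
#' @param pca pCa grid; must span both sides of `pca50`.
#' @param seed integer seed.
#' @return A data frame with columns `pca` and `velocity`.
#' @examples
#' pts <- gen_ivma_points(noise_sd = 0, seed = 1)
#' fit_hill(pts)   # recovers v_max = 1, pca50 = 6, n_h = 3
#' @export
gen_ivma_points <- function(v_max = 1, pca50 = 6, n_h = 3, noise_sd = 0,
                            pca = seq(7.0, 4.5, length.out = 21),
                            seed = 1L) {
  stopifnot(v_max > 0, n_h > 0, noise_sd >= 0, length(pca) >= 4L)
  if (min(pca) >= pca50 || max(pca) <= pca50)
    stop("pca grid must span both sides of half-activation (pca50)")
  v <- v_max / (1 + 10^(n_h * (pca - pca50)))
  if (noise_sd > 0) v <- v + local_rnorm(length(v), noise_sd, seed)
  data.frame(pca = pca, velocity = v)
}

#' Generate a synthetic isometric twitch trace
#'
#' Builds a smooth two-time-constant twitch
#' `baseline + A * (1 - exp(-t/tau_rise))^8 * exp(-t/tau_decay)`
#' (sigmoidal rise, exponential relaxation) whose noiseless peak equals
#' `f_peak` above baseline at time `ttp` and whose half-relaxation time
#' equals `rt50`; the two time constants are obtained by root-finding. A
#' 50 ms pre-stimulus baseline segment is included (stimulus at time 0).
#' Additive Gaussian noise; deterministic given `seed`. Combinations of
#' `ttp` and `rt50` the shape family cannot attain (roughly
#' `rt50 < 0.5 * ttp`), or an `rt50` below the sampling interval, raise an
#' error.
#'
#' @param f_peak peak force above baseline.
#' @param ttp time from stimulus to peak, seconds.
#' @param rt50 time from peak to 50% relaxation, seconds.
#' @param baseline resting force level.
#' @param noise_sd additive Gaussian standard deviation.
#' @param sample_dt sampling interval, seconds.
#' @param duration record length after the stimulus, seconds.
#' @param seed integer seed.
#' @return A data frame (`time`, `force`) with attribute
#'   `stimulus_time = 0`; ready for [twitch_metrics()].
#' @examples
#' tw <- gen_twitch_trace(f_peak = 1, ttp = 0.15, rt50 = 0.12)
#' twitch_metrics(tw)
#' @export
gen_twitch_trace <- function(f_peak = 1, ttp = 0.15, rt50 = 0.12,
                             baseline = 0, noise_sd = 0, sample_dt = 0.002,
                             duration = 1, seed = 1L) {
  stopifnot(f_peak > 0, ttp > 0, rt50 > 0, noise_sd >= 0, sample_dt > 0)
  if (ttp >= duration) stop("ttp must be smaller than duration")
  if (rt50 < sample_dt)
    stop("rt50 is not resolvable at this sample_dt (rt50 < sample_dt)")
  taus <- solve_twitch_taus(ttp, rt50)
  shape <- function(t) (1 - exp(-t / taus$tau_r))^8 * exp(-t / taus$tau_d)
  amp <- f_peak / shape(ttp)
  tt <- seq(-0.05, duration, by = sample_dt)
  ff <- baseline + ifelse(tt < 0, 0, amp * shape(pmax(tt, 0)))
  if (noise_sd > 0) ff <- ff + local_rnorm(length(ff), noise_sd, seed)
  out <- data.frame(time = tt, force = ff)
  attr(out, "stimulus_time") <- 0
  attr(out, "generator") <- list(f_peak = f_peak, ttp = ttp, rt50 = rt50,
                                 baseline = baseline, noise_sd = noise_sd,
                                 tau_rise = taus$tau_r,
                                 tau_decay = taus$tau_d)
  out
}

# Find (tau_r, tau_d) such that the pulse (1-exp(-t/tau_r))^p exp(-t/tau_d)
# (p = 8, a sharp sigmoidal rise) peaks at ttp and decays to half its peak
# rt50 seconds later. The peak time tau_r*log((p*tau_d + tau_r)/tau_r)
# increases in tau_r and spans (0, p*tau_d), pinning tau_r for each tau_d;
# the resulting rt50 is then monotone increasing in tau_d, so one outer
# bisection suffices. The attainable floor is rt50 ~ 0.46*ttp.
TWITCH_RISE_POWER <- 8

solve_twitch_taus <- function(ttp, rt50) {
  p <- TWITCH_RISE_POWER
  rise_for_peak <- function(tau_d) {
    if (ttp >= p * tau_d * (1 - 1e-9))
      stop("infeasible (ttp, rt50) combination for the twitch shape family")
    stats::uniroot(function(tr) tr * log((p * tau_d + tr) / tr) - ttp,
                   lower = ttp * 1e-9, upper = 1e7 * tau_d,
                   tol = 1e-14)$root
  }
  rt50_of <- function(tau_d) {
    tau_r <- rise_for_peak(tau_d)
    shape <- function(t) (1 - exp(-t / tau_r))^p * exp(-t / tau_d)
    half <- shape(ttp) / 2
    upper <- ttp + tau_d * 80
    stats::uniroot(function(t) shape(t) - half, lower = ttp, upper = upper,
                   tol = 1e-13)$root - ttp
  }
  lo <- ttp / p * 1.0001
  hi <- max(rt50, ttp) * 50
  r_lo <- tryCatch(rt50_of(lo), error = function(e) NA_real_)
  r_hi <- tryCatch(rt50_of(hi), error = function(e) NA_real_)
  if (!is.finite(r_lo) || !is.finite(r_hi) || rt50 <= r_lo || rt50 >= r_hi)
    stop("infeasible (ttp, rt50) combination for the twitch shape family")
  tau_d <- stats::uniroot(function(td) rt50_of(td) - rt50, lower = lo,
                          upper = hi, tol = 1e-12)$root
  list(tau_r = rise_for_peak(tau_d), tau_d = tau_d)
}

# Gaussian draws from a private RNG stream; leaves the global RNG state
# untouched.
local_rnorm <- function(n, sd, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  stats::rnorm(n, 0, sd)
}
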