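# Experiment protocols: steady-state force-pCa sweeps with Hill fitting,
# and isometric twitches driven by a parametric calcium transient.

#' Steady-state force-pCa sweep
#'
#' For each pCa value, simulates the chain at constant calcium and estimates
#' the steady-state force as the exact time-average of the ensemble M-state
#' fraction over the final portion of the record (default: the last 2.5 s of
#' a 10 s simulation). The standard error is computed from the spread of
#' per-trajectory window averages. A drift check compares the two halves of
#' the averaging window; rows whose halves differ by more than 3 standard
#' errors are flagged (`drift = TRUE`) with a warning.
#'
#' @param params a [param_set()].
#' @param pca_grid pCa values (default 21 points spanning 7.0 to 4.5,
#'   covering the sigmoid of the force-pCa relation). Values must lie in
#'   `[4, 9]`.
#' @param n_traj trajectories per pCa point.
#' @param seed integer master seed; point `i` uses `seed + i - 1`.
#' @param duration seconds simulated per point.
#' @param window `c(t0, t1)` averaging window in seconds.
#' @return A data frame with columns `pca`, `ca` (micromolar), `force`,
#'   `se`, and `drift` (logical non-convergence flag).
#' @export
run_pca_sweep <- function(params, pca_grid = seq(7.0, 4.5, length.out = 21),
                          n_traj = 120L, seed = 1L, duration = 10,
                          window = c(7.5, 10)) {
  stopifnot(inherits(params, "tf_params"))
  if (length(pca_grid) == 0L) stop("pca_grid must be nonempty")
  if (any(pca_grid < 4 | pca_grid > 9))
    stop("pca_grid values must lie in [4, 9]")
  stopifnot(window[2] <= duration, window[1] < window[2])
  half <- mean(window)
  out <- lapply(seq_along(pca_grid), function(i) {
    ca <- 10^(-pca_grid[i]) * 1e6  # micromolar
    tr <- simulate_ensemble(params, ca, duration = duration,
                            sample_dt = max(0.002, duration / 2000),
                            n_traj = n_traj, seed = seed + i - 1L,
                            window = window, record_occupancy = FALSE)
    f <- mean(tr$window_means)
    se <- stats::sd(tr$window_means) / sqrt(n_traj)
    # drift check on the averaged trace over the two window halves
    in1 <- tr$time >= window[1] & tr$time < half
    in2 <- tr$time >= half & tr$time <= window[2]
    drift <- abs(mean(tr$force[in2]) - mean(tr$force[in1])) >
      3 * max(se, .Machine$double.eps)
    data.frame(pca = pca_grid[i], ca = ca, force = f, se = se, drift = drift)
  })
  out <- do.call(rbind, out)
  if (any(out$drift))
    warning("steady-state averaging window shows drift at pCa ",
            paste(format(out$pca[out$drift]), collapse = ", "))
  out
}

#' Fit the Hill equation to a force- or velocity-pCa point set
#'
#' Least-squares fit of `response = f_max * ca^n_h / (ca^n_h + ca50^n_h)`
#' (equivalently `f_max / (1 + 10^(n_h * (pca - pca50)))`), via
#' Levenberg-Marquardt. The half-activation point is reported as
#' `pca50 = -log10(ca50 in molar)`.
#'
#' @param points data frame with columns `pca` and a response column (the
#'   second column, typically `force` or `velocity`).
#' @return An object of class `tf_hill`: list with `f_max`, `pca50`, `n_h`,
#'   `residual_sse`, and the fitted `nls` model.
#' @examples
#' pts <- data.frame(pca = seq(7, 5, by = -0.25))
#' pts$force <- 1 / (1 + 10^(3 * (pts$pca - 6)))
#' fit_hill(pts)
#' @export
fit_hill <- function(points) {
  if (!is.data.frame(points) || ncol(points) < 2L)
    stop("points must be a data frame with pCa and response columns")
  pca <- points[["pca"]]
  if (is.null(pca)) pca <- points[[1]]
  resp <- points[[setdiff(names(points), "pca")[1]]]
  if (length(pca) < 4L) stop("need at least 4 points to fit the Hill equation")
  rng <- range(resp)
  if (!all(is.finite(resp)) || diff(rng) <= max(1e-12, 0.02 * max(abs(rng))))
    stop("Hill fit failure: response is flat or non-finite")
  half <- rng[1] + diff(rng) / 2
  above <- resp > half
  if (all(above) || !any(above))
    stop("Hill fit failure: points do not span half-activation")

  start <- list(f_max = max(resp),
                pca50 = pca[which.min(abs(resp - half))],
                n_h = 2)
  dat <- data.frame(pca = pca, resp = resp)
  fit <- tryCatch(
    minpack.lm::nlsLM(resp ~ f_max / (1 + 10^(n_h * (pca - pca50))),
                      data = dat, start = start,
                      lower = c(f_max = 0, pca50 = 3, n_h = 1e-3),
                      upper = c(f_max = Inf, pca50 = 10, n_h = 50),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Hill fit failure: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["n_h"]] <= 0) stop("Hill fit failure: non-positive Hill coefficient")
  structure(list(f_max = unname(cf[["f_max"]]),
                 pca50 = unname(cf[["pca50"]]),
                 n_h = unname(cf[["n_h"]]),
                 residual_sse = sum(stats::resid(fit)^2),
                 model = fit), class = "tf_hill")
}

#' @export
print.tf_hill <- function(x, ...) {
  cat(sprintf("Hill fit: f_max = %.4g, pCa50 = %.4f, n_H = %.3f (SSE %.3g)\n",
              x$f_max, x$pca50, x$n_h, x$residual_sse))
  invisible(x)
}

#' Parametric intracellular calcium transient
#'
#' Builds a smooth difference-of-exponentials calcium pulse rising from a
#' diastolic level to a specified peak and relaxing back: for `t >= 0`,
#' `ca(t) = diastolic + A * (exp(-t/decay_tau) - exp(-t/tau_rise))`, with
#' the rise time constant solved so the maximum occurs exactly at
#' `time_to_peak` and `A` scaled so the maximum equals `peak`; `ca(t) =
#' diastolic` for `t < 0`. Defaults emulate a human cardiomyocyte transient
#' rising from 0.1 to 1 micromolar.
#'
#' @param diastolic resting calcium, micromolar.
#' @param peak peak calcium, micromolar (must exceed `diastolic`).
#' @param time_to_peak seconds from stimulus to the calcium peak.
#' @param decay_tau decay time constant, seconds.
#' @param duration nominal record length, seconds (stored for protocols).
#' @return An object of class `tf_transient`: a list with the spec fields
#'   and `fun`, the vectorized function time (s) -> micromolar.
#' @examples
#' tr <- ca_transient()
#' tr$fun(0)      # 0.1
#' tr$fun(0.05)   # 1.0
#' @export
ca_transient <- function(diastolic = 0.1, peak = 1, time_to_peak = 0.05,
                         decay_tau = 0.15, duration = 1) {
  if (!is.finite(diastolic) || diastolic < 0) stop("diastolic must be >= 0")
  if (!is.finite(peak) || peak <= diastolic)
    stop("peak calcium must exceed the diastolic level")
  if (time_to_peak <= 0 || time_to_peak >= duration)
    stop("time_to_peak must lie in (0, duration)")
  if (decay_tau <= 0) stop("decay_tau must be > 0")
  tau_r <- solve_rise_tau(time_to_peak, decay_tau)
  amp <- (peak - diastolic) /
    (exp(-time_to_peak / decay_tau) - exp(-time_to_peak / tau_r))
  fun <- function(t) {
    ifelse(t < 0, diastolic,
           diastolic + amp * (exp(-t / decay_tau) - exp(-t / tau_r)))
  }
  structure(list(diastolic = diastolic, peak = peak,
                 time_to_peak = time_to_peak, decay_tau = decay_tau,
                 duration = duration, tau_rise = tau_r, amplitude = amp,
                 fun = fun), class = "tf_transient")
}

# Rise time constant such that A(exp(-t/tau_d) - exp(-t/tau_r)) peaks at tp:
# the peak of the difference is at t* = ln(tau_d/tau_r) * tau_d tau_r /
# (tau_d - tau_r), monotone increasing in tau_r; solved by bisection.
solve_rise_tau <- function(tp, tau_d) {
  tstar <- function(tau_r) {
    if (abs(tau_r - tau_d) < 1e-12 * tau_d) return(tau_d)
    log(tau_d / tau_r) * tau_d * tau_r / (tau_d - tau_r)
  }
  if (tstar(tau_d * (1 - 1e-9)) <= tp)
    stop("time_to_peak too long for decay_tau (needs time_to_peak < decay_tau)")
  lower <- tp * 1e-3
  while (tstar(lower) >= tp && lower > 1e-15) lower <- lower / 10
  stats::uniroot(function(x) tstar(x) - tp,
                 lower = lower, upper = tau_d * (1 - 1e-9),
                 tol = 1e-14)$root
}

#' Simulate an averaged isometric twitch
#'
#' Equilibrates the chain at the diastolic calcium level, applies the
#' calcium transient starting at time 0 (the stimulus), and returns the
#' average of `n_repeats` independent ensemble traces (paper-scale defaults:
#' 1920 trajectories, averaged over 10 repeats). A 50 ms pre-stimulus
#' baseline segment is recorded for metric extraction.
#'
#' @param params a [param_set()].
#' @param transient a [ca_transient()].
#' @param n_traj trajectories per ensemble.
#' @param n_repeats ensembles averaged (repeat `r` uses seed
#'   `seed + 7919 * (r - 1)`).
#' @param seed integer master seed.
#' @param sample_dt recording interval, seconds.
#' @param burn_in equilibration time at diastolic calcium before recording.
#' @param pre_record seconds of pre-stimulus baseline kept in the trace.
#' @return A data frame (`time`, `force`, `se`) of class
#'   `c("tf_twitch", "data.frame")`, with attributes `seeds`, `n_traj`,
#'   `stimulus_time` (0) and `transient`.
#' @export
simulate_twitch <- function(params, transient = ca_transient(),
                            n_traj = 1920L, n_repeats = 10L, seed = 1L,
                            sample_dt = 0.002, burn_in = 0.5,
                            pre_record = 0.05) {
  stopifnot(inherits(params, "tf_params"), inherits(transient, "tf_transient"))
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  if (burn_in < pre_record) stop("burn_in must cover the pre-stimulus record")
  seeds <- as.integer(seed) + 7919L * (seq_len(n_repeats) - 1L)
  traces <- lapply(seeds, function(s)
    simulate_ensemble(params, transient$fun, duration = transient$duration,
                      sample_dt = sample_dt, n_traj = n_traj, seed = s,
                      burn_in = burn_in, record_from = -pre_record,
                      record_occupancy = FALSE))
  force <- rowMeans(vapply(traces, `[[`, numeric(length(traces[[1]]$force)),
                           "force"))
  se <- sqrt(rowMeans(vapply(traces, function(x) x$se^2,
                             numeric(length(traces[[1]]$se)))) / n_repeats)
  out <- data.frame(time = traces[[1]]$time, force = force, se = se)
  class(out) <- c("tf_twitch", "data.frame")
  attr(out, "seeds") <- seeds
  attr(out, "n_traj") <- n_traj
  attr(out, "stimulus_time") <- 0
  attr(out, "transient") <- transient[c("diastolic", "peak", "time_to_peak",
                                        "decay_tau", "duration")]
  out
}

#' Extract twitch metrics from a force trace
#'
#' Computes the standard isometric twitch characteristics: peak force above
#' baseline (`f_peak`), time from stimulus to peak (`ttp`), time from the
#' peak to 50% relaxation toward baseline (`rt50`), and the normalized
#' force-time integral (`nfti`, the integral of force above baseline from
#' the stimulus to the end of the record divided by `f_peak`; units of
#' seconds). The baseline is the mean force over the 50 ms preceding the
#' stimulus (or the first sample if no pre-stimulus data exist). The trace
#' is linearly interpolated to locate the half-relaxation crossing. If the
#' trace never decays below half-relaxation, `rt50` is `NA` and the result
#' is flagged (`incomplete_relaxation = TRUE`) rather than an error.
#'
#' @param trace data frame with `time` and `force` columns (e.g. from
#'   [simulate_twitch()] or [gen_twitch_trace()]).
#' @param stimulus_time stimulus time in seconds (default the trace's
#'   `stimulus_time` attribute, else 0).
#' @param baseline_window seconds before the stimulus used for the baseline.
#' @param smooth_window optional low-pass window in seconds: the force is
#'   replaced by a centered running mean over this span before metrics are
#'   extracted (edge samples use shrunken windows). Useful for noisy
#'   measured records; 0 (default) disables smoothing.
#' @return An object of class `tf_twitch_metrics`: list with `f_peak`,
#'   `ttp`, `rt50`, `nfti`, `baseline`, `incomplete_relaxation`.
#' @examples
#' tri <- data.frame(time = c(0, 0.1, 0.3), force = c(0, 1, 0))
#' twitch_metrics(tri)  # ttp 0.1, rt50 0.1, nfti 0.15
#' @export
twitch_metrics <- function(trace, stimulus_time = NULL,
                           baseline_window = 0.05, smooth_window = 0) {
  if (is.null(stimulus_time))
    stimulus_time <- attr(trace, "stimulus_time") %||% 0
  tt <- trace$time; ff <- trace$force
  if (is.null(tt) || is.null(ff)) stop("trace needs time and force columns")
  if (is.unsorted(tt, strictly = TRUE)) stop("trace time must be increasing")
  if (smooth_window > 0) {
    k <- max(1L, round(smooth_window / stats::median(diff(tt)) / 2))
    ff <- running_mean(ff, k)
  }

  pre <- tt < stimulus_time & tt >= stimulus_time - baseline_window
  baseline <- if (any(pre)) mean(ff[pre]) else ff[1]

  post <- tt >= stimulus_time
  tp <- tt[post]; fp <- ff[post]
  ipk <- which.max(fp)
  f_peak <- fp[ipk] - baseline
  if (f_peak <= 0) stop("trace has no force excursion above baseline")
  t_peak <- tp[ipk]
  ttp <- t_peak - stimulus_time

  half <- baseline + f_peak / 2
  # project the relaxation phase onto a monotone-decreasing curve before
  # locating the half-crossing: relaxation is physically monotone, and the
  # isotonic projection makes the threshold crossing robust to residual
  # noise on shallow tails
  decay_t <- tp[ipk:length(tp)]
  decay_f <- -stats::isoreg(decay_t, -fp[ipk:length(fp)])$yf
  after <- which(decay_f <= half)
  if (length(after) == 0L || after[1] == 1L) {
    rt50 <- if (length(after) == 0L) NA_real_ else 0
    incomplete <- length(after) == 0L
  } else {
    j <- after[1]
    # linear interpolation between the bracketing samples
    denom <- decay_f[j] - decay_f[j - 1]
    t_cross <- if (denom == 0) decay_t[j] else
      decay_t[j - 1] + (half - decay_f[j - 1]) * (decay_t[j] - decay_t[j - 1]) / denom
    rt50 <- t_cross - t_peak
    incomplete <- FALSE
  }
  fti <- sum(diff(tp) * (utils::head(fp - baseline, -1) +
                           utils::tail(fp - baseline, -1)) / 2)
  structure(list(f_peak = f_peak, ttp = ttp, rt50 = rt50,
                 nfti = fti / f_peak, baseline = baseline,
                 incomplete_relaxation = incomplete),
            class = "tf_twitch_metrics")
}

#' @export
print.tf_twitch_metrics <- function(x, ...) {
  cat(sprintf(
    "Twitch metrics: F_peak %.4g, TTP %.4g s, RT50 %s s, nFTI %.4g s%s\n",
    x$f_peak, x$ttp,
    if (is.na(x$rt50)) "NA" else sprintf("%.4g", x$rt50), x$nfti,
    if (x$incomplete_relaxation) " [incomplete relaxation]" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Centered running mean with half-width k; windows shrink symmetrically at
# the edges so no samples are lost.
running_mean <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
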