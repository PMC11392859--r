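test_that("Hill fitting recovers noiseless parameters to high precision", {
  pca <- seq(7, 5, by = -0.2)
  pts <- data.frame(pca = pca, force = 1 / (1 + 10^(3 * (pca - 6))))
  fit <- fit_hill(pts)
  expect_equal(fit$f_max, 1, tolerance = 1e-6)
  expect_equal(fit$pca50, 6, tolerance = 1e-6)
  expect_equal(fit$n_h, 3, tolerance = 1e-6)
  expect_lt(fit$residual_sse, 1e-12)
})

test_that("Hill fitting fails loudly on degenerate data", {
  pca <- seq(7, 5, by = -0.25)
  expect_error(fit_hill(data.frame(pca = pca, force = rep(0, length(pca)))),
               "flat")
  expect_error(fit_hill(data.frame(pca = pca, force = rep(0.7, length(pca)))),
               "flat")
  expect_error(fit_hill(data.frame(pca = 6, force = 1)), "4 points")
  # all points on one side of half-activation
  half <- data.frame(pca = seq(5.2, 5, by = -0.05))
  half$force <- 1 / (1 + 10^(3 * (half$pca - 6)))
  half$force <- half$force - min(half$force) * 0  # keep shape
  expect_error(fit_hill(half), "Hill fit failure")
})

test_that("Hill fitting is accurate under measurement noise", {
  # noisy point sets at sigma = 0.02: median |pCa50 error| below 0.05
  errs <- vapply(1:100, function(i) {
    pts <- gen_ivma_points(v_max = 1, pca50 = 6, n_h = 3, noise_sd = 0.02,
                           pca = seq(7, 5, length.out = 10), seed = i)
    fit_hill(pts)$pca50 - 6
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.05)
})

test_that("the calcium transient honors its defining endpoints", {
  tr <- ca_transient()
  expect_equal(tr$fun(0), 0.1)
  expect_equal(tr$fun(-0.5), 0.1)
  tt <- seq(0, 1, by = 1e-4)
  ca <- tr$fun(tt)
  expect_equal(max(ca), 1, tolerance = 1e-6)
  expect_equal(tt[which.max(ca)], 0.05, tolerance = 1e-3)
  # starts and ends at the diastolic level within 2%
  expect_lt(abs(ca[length(ca)] - 0.1) / 0.1, 0.02)
  # slow-decay limit is non-decreasing over the record
  slow <- ca_transient(decay_tau = 1e6, duration = 1)
  expect_true(all(diff(slow$fun(seq(0, 1, by = 1e-3))) >= -1e-8))
  expect_error(ca_transient(peak = 0.05), "exceed")
})

test_that("twitch metrics match closed-form values on a triangular pulse", {
  tri <- data.frame(time = c(seq(0, 0.1, by = 0.005),
                             seq(0.105, 0.3, by = 0.005)))
  tri$force <- ifelse(tri$time <= 0.1, tri$time / 0.1,
                      (0.3 - tri$time) / 0.2)
  m <- twitch_metrics(tri, stimulus_time = 0)
  expect_equal(m$f_peak, 1, tolerance = 1e-9)
  expect_equal(m$ttp, 0.1, tolerance = 1e-9)
  expect_equal(m$rt50, 0.1, tolerance = 1e-9)
  expect_equal(m$nfti, 0.15, tolerance = 1e-3)  # trapezoid vs exact area
  expect_false(m$incomplete_relaxation)

  # scaling the trace doubles the peak and leaves timings unchanged
  tri2 <- tri
  tri2$force <- 2 * tri$force
  m2 <- twitch_metrics(tri2, stimulus_time = 0)
  expect_equal(m2$f_peak, 2 * m$f_peak)
  expect_equal(m2$ttp, m$ttp)
  expect_equal(m2$rt50, m$rt50)
  expect_equal(m2$nfti, m$nfti, tolerance = 1e-9)

  # a nonzero baseline is subtracted using the pre-stimulus window
  shifted <- data.frame(time = c(seq(-0.05, -0.005, by = 0.005), tri$time),
                        force = c(rep(0.3, 10), tri$force + 0.3))
  m3 <- twitch_metrics(shifted, stimulus_time = 0)
  expect_equal(m3$baseline, 0.3, tolerance = 1e-9)
  expect_equal(m3$f_peak, 1, tolerance = 1e-9)
  expect_equal(m3$rt50, 0.1, tolerance = 1e-9)
})

test_that("incomplete relaxation is flagged rather than an error", {
  rise <- data.frame(time = seq(0, 0.5, by = 0.01))
  rise$force <- pmin(rise$time / 0.1, 1)
  m <- twitch_metrics(rise, stimulus_time = 0)
  expect_true(m$incomplete_relaxation)
  expect_true(is.na(m$rt50))
  expect_gt(m$nfti, 0)
})

test_that("steady-state sweeps are shaped and Ca-monotone", {
  grid <- c(8, 5)
  sw <- suppressWarnings(run_pca_sweep(set1, grid, n_traj = 24, seed = 3,
                                       duration = 1.5,
                                       window = c(0.75, 1.5)))
  expect_equal(nrow(sw), length(grid))
  expect_named(sw, c("pca", "ca", "force", "se", "drift"))
  # activation at pCa 5 exceeds pCa 8 beyond 3 combined standard errors
  expect_gt(sw$force[sw$pca == 5] - sw$force[sw$pca == 8],
            3 * sqrt(sum(sw$se^2)))
  expect_error(run_pca_sweep(set1, numeric(0)), "nonempty")
  expect_error(run_pca_sweep(set1, c(5, 10)), "4, 9")
})

test_that("twitch simulation is reproducible and reduces to one ensemble", {
  p <- short_params(set2, 6L)
  tw1 <- simulate_twitch(p, n_traj = 40, n_repeats = 1, seed = 9,
                         burn_in = 0.2)
  # n_repeats = 1 equals a single ensemble call with the same seed
  ref <- simulate_ensemble(p, ca_transient()$fun, duration = 1,
                           sample_dt = 0.002, n_traj = 40, seed = 9,
                           burn_in = 0.2, record_from = -0.05,
                           record_occupancy = FALSE)
  expect_equal(tw1$force, ref$force)
  expect_identical(simulate_twitch(p, n_traj = 40, n_repeats = 2, seed = 9,
                                   burn_in = 0.2)$force,
                   simulate_twitch(p, n_traj = 40, n_repeats = 2, seed = 9,
                                   burn_in = 0.2)$force)
})

test_that("a wild-type twitch relaxes back to its diastolic baseline", {
  tw <- simulate_twitch(set2, n_traj = 96, n_repeats = 2, seed = 21,
                        burn_in = 0.5)
  m <- twitch_metrics(tw)
  expect_false(m$incomplete_relaxation)
  tail_idx <- tw$time > 0.9
  tail_force <- mean(tw$force[tail_idx])
  tail_se <- sqrt(mean(tw$se[tail_idx]^2) / sum(tail_idx))
  # within 3 SE of the pre-stimulus baseline by the end of the record
  expect_lt(abs(tail_force - m$baseline), max(3 * tail_se, 0.01))
})
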