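# A hand-built expression sweep with the class attached, for inference
# tests that need no simulation
fake_sweep <- function() {
  out <- data.frame(
    expression = seq(0, 1, by = 0.1),
    f_peak = seq(0.15, 0.10, length.out = 11),
    ttp = 0.07, rt50 = 0.16, nfti = 0.26)
  out$pct_f_peak <- 100 * (out$f_peak - out$f_peak[1]) / out$f_peak[1]
  out$pct_ttp <- 0
  out$pct_rt50 <- c(0, -14, -18, -22, -26, -30, -26, -22, -18, -14, -10)
  out$pct_nfti <- c(0, -4, -8, -11, -14, -17, -15, -13, -11, -9, -7)
  class(out) <- c("tf_expression_sweep", "data.frame")
  out
}

test_that("a single-cell grid search returns that cell as the argmin", {
  gs <- suppressWarnings(grid_search_ivma(
    set1, gamma_scales = 0.5, kbc_scales = 0.74,
    targets = ivma_targets(-0.2, -10),
    pca_grid = c(7, 6.2, 5.6, 5, 4.5),
    n_traj = 10, seed = 1, duration = 1, window = c(0.5, 1)))
  expect_equal(unname(gs$argmin), c(0.5, 0.74))
  expect_equal(dim(gs$sse), c(1L, 1L))
  expect_true(is.finite(gs$sse[1, 1]) && gs$sse[1, 1] >= 0)
  expect_equal(nrow(gs$cells), 1L)
})

test_that("grid-search input validation", {
  t0 <- ivma_targets(-0.2, -10)
  expect_error(grid_search_ivma(set1, numeric(0), 1, t0), "nonempty")
  expect_error(grid_search_ivma(set1, c(-0.5, 1), 1, t0), "> 0")
  expect_error(ivma_targets(NA, 1), "is.finite")
})

test_that("expression inference round-trips every sweep row", {
  sw <- fake_sweep()
  for (i in seq_len(nrow(sw))) {
    targ <- twitch_delta_targets(sw$pct_f_peak[i], sw$pct_rt50[i],
                                 sw$pct_nfti[i])
    expect_equal(infer_expression(sw, targ)$best_expression,
                 sw$expression[i])
  }
  # all-zero targets select the wild-type row
  expect_equal(
    infer_expression(sw, twitch_delta_targets(0, 0, 0))$best_expression, 0)
})

test_that("the admissible set honors SEM windows and contains the best", {
  sw <- fake_sweep()
  targ <- twitch_delta_targets(-15, -25, -13,
                               sem = c(pct_f_peak = 8, pct_rt50 = 4,
                                       pct_nfti = 4))
  res <- infer_expression(sw, targ)
  expect_true(all(res$admissible %in% sw$expression))
  expect_true(res$best_expression %in% res$admissible)
  expect_false(res$admissible_empty)
  # every admissible row really satisfies all three windows
  for (e in res$admissible) {
    row <- sw[sw$expression == e, ]
    expect_lt(abs(row$pct_f_peak - -15), 8 + 1e-9)
    expect_lt(abs(row$pct_rt50 - -25), 4 + 1e-9)
    expect_lt(abs(row$pct_nfti - -13), 4 + 1e-9)
  }
  # impossible windows flag an empty set but still report a best match
  hopeless <- twitch_delta_targets(50, 50, 50,
                                   sem = c(pct_f_peak = 1, pct_rt50 = 1,
                                           pct_nfti = 1))
  res2 <- infer_expression(sw, hopeless)
  expect_true(res2$admissible_empty)
  expect_length(res2$admissible, 0)
  expect_error(infer_expression(sw[1:2, ], targ), "3 expression")
})

test_that("bootstrap comparison is deterministic and handles edge cases", {
  a <- c(1.1, 0.9, 1.3, 1.0, 0.8)
  b <- c(0.2, 0.5, 0.1, 0.4, 0.3)
  r1 <- bootstrap_compare(a, b, n_resamples = 2000, seed = 7)
  r2 <- bootstrap_compare(a, b, n_resamples = 2000, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$mean_diff, mean(a) - mean(b))
  expect_equal(r1$n_resamples, 2000L)

  same <- bootstrap_compare(a, a, n_resamples = 2000, seed = 1)
  expect_equal(same$mean_diff, 0)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)

  flat <- bootstrap_compare(rep(2, 5), rep(2, 5), n_resamples = 500,
                            seed = 1)
  expect_true(flat$degenerate)
  expect_equal(unname(diff(flat$ci)), 0)
  expect_true(is.na(flat$p_value))
  expect_error(bootstrap_compare(1:2, 1:5), "at least 3")
})

test_that("bootstrap detects a known group separation reliably", {
  # Gaussian groups (n = 20, means 0 vs 1, sd = 0.5): the interval should
  # exclude zero in at least 95% of replicate experiments
  excludes <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    a <- rnorm(20, 0, 0.5)
    b <- rnorm(20, 1, 0.5)
    ci <- bootstrap_compare(a, b, n_resamples = 1000, seed = i)$ci
    ci[2] < 0 || ci[1] > 0
  }, logical(1))
  expect_gte(mean(excludes), 0.95)
})

test_that("bootstrap default resample count follows the protocol", {
  expect_equal(formals(bootstrap_compare)$n_resamples, 10000L)
})
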