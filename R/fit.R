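# Fitting mutation-induced parameter changes and inferring mutant
# expression level from twitch phenotypes.

#' Motility-assay fitting targets
#'
#' The two quantities used to fit mutant parameter scalings against in
#' vitro motility data: the absolute change in calcium sensitivity
#' (`delta_pca50`, mutant minus wild type, pCa units) and the percent change
#' in maximum sliding velocity (`pct_delta_vmax`). Model maximum velocity is
#' taken proportional to the steady-state crossbridge (M-state) level, so
#' the Hill-fit `f_max` stands in for `V_max`.
#'
#' @param delta_pca50 absolute pCa50 change (mutant - WT).
#' @param pct_delta_vmax percent change in maximum velocity.
#' @return An object of class `tf_ivma_targets`.
#' @export
ivma_targets <- function(delta_pca50, pct_delta_vmax) {
  stopifnot(is.finite(delta_pca50), is.finite(pct_delta_vmax))
  structure(list(delta_pca50 = delta_pca50, pct_delta_vmax = pct_delta_vmax),
            class = "tf_ivma_targets")
}

#' Grid search for mutant parameter scalings
#'
#' Evaluates every combination of `gamma` and `K_BC` scaling factors: for
#' each cell the steady-state force-pCa sweep is run with the scaled
#' parameters, fitted with the Hill equation, and compared with the
#' wild-type fit to obtain the predicted (`delta_pca50`, `pct_delta_vmax`)
#' pair. The sum of squared errors against the targets is accumulated with
#' each term divided by the squared target magnitude so that pCa units and
#' percentages are commensurate (a target of exactly 0 falls back to an
#' unnormalized term). Cells whose Hill fit fails are assigned infinite SSE
#' and the search continues.
#'
#' @param wt wild-type [param_set()].
#' @param gamma_scales,kbc_scales grid axes of multiplicative scalings
#'   (defaults: ten values each, `gamma` 0.1..1.0 and `K_BC` 0.55..1.0).
#' @param targets a [ivma_targets()].
#' @param pca_grid,n_traj,seed,duration,window passed to [run_pca_sweep()];
#'   every cell reuses the same seed so cell differences reflect parameters,
#'   not sampling.
#' @return An object of class `tf_grid_search`: list with the axes, the
#'   `sse` matrix (rows = gamma scales, columns = K_BC scales), `argmin`
#'   (named vector `gamma_scale`, `kbc_scale`), the per-cell summary data
#'   frame `cells`, and the wild-type Hill fit `wt_fit`.
#' @export
grid_search_ivma <- function(wt,
                             gamma_scales = seq(0.1, 1.0, length.out = 10),
                             kbc_scales = seq(0.55, 1.0, length.out = 10),
                             targets,
                             pca_grid = seq(7.0, 4.5, length.out = 13),
                             n_traj = 60L, seed = 1L, duration = 10,
                             window = c(7.5, 10)) {
  stopifnot(inherits(wt, "tf_params"), inherits(targets, "tf_ivma_targets"))
  if (length(gamma_scales) == 0L || length(kbc_scales) == 0L)
    stop("scale axes must be nonempty")
  if (any(gamma_scales <= 0) || any(kbc_scales <= 0))
    stop("scales must be > 0")

  wt_sweep <- run_pca_sweep(wt, pca_grid, n_traj, seed, duration, window)
  wt_fit <- fit_hill(wt_sweep[, c("pca", "force")])

  cells <- expand.grid(gamma_scale = gamma_scales, kbc_scale = kbc_scales,
                       KEEP.OUT.ATTRS = FALSE)
  cells$pca50 <- cells$f_max <- cells$n_h <- NA_real_
  cells$delta_pca50 <- cells$pct_delta_vmax <- NA_real_
  sse <- matrix(Inf, nrow = length(gamma_scales), ncol = length(kbc_scales),
                dimnames = list(format(gamma_scales), format(kbc_scales)))
  norm_dp <- if (targets$delta_pca50 != 0) targets$delta_pca50^2 else 1
  norm_dv <- if (targets$pct_delta_vmax != 0) targets$pct_delta_vmax^2 else 1

  for (k in seq_len(nrow(cells))) {
    mut <- apply_mutation(wt, mutation_spec(cells$gamma_scale[k],
                                            cells$kbc_scale[k], 1))
    sw <- run_pca_sweep(mut, pca_grid, n_traj, seed, duration, window)
    fit <- tryCatch(fit_hill(sw[, c("pca", "force")]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    i <- match(cells$gamma_scale[k], gamma_scales)
    j <- match(cells$kbc_scale[k], kbc_scales)
    dp <- fit$pca50 - wt_fit$pca50
    dv <- 100 * (fit$f_max - wt_fit$f_max) / wt_fit$f_max
    cells$pca50[k] <- fit$pca50; cells$f_max[k] <- fit$f_max
    cells$n_h[k] <- fit$n_h
    cells$delta_pca50[k] <- dp; cells$pct_delta_vmax[k] <- dv
    sse[i, j] <- (dp - targets$delta_pca50)^2 / norm_dp +
      (dv - targets$pct_delta_vmax)^2 / norm_dv
  }
  if (all(!is.finite(sse))) stop("Hill fit failed in every grid cell")
  am <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  structure(list(gamma_scales = gamma_scales, kbc_scales = kbc_scales,
                 sse = sse,
                 argmin = c(gamma_scale = gamma_scales[am[1]],
                            kbc_scale = kbc_scales[am[2]]),
                 cells = cells, wt_fit = wt_fit),
            class = "tf_grid_search")
}

#' @export
print.tf_grid_search <- function(x, ...) {
  cat("IVMA grid search:", length(x$gamma_scales), "x",
      length(x$kbc_scales), "cells\n")
  cat(sprintf("  argmin: gamma_scale = %.3g, kbc_scale = %.3g (SSE %.4g)\n",
              x$argmin[["gamma_scale"]], x$argmin[["kbc_scale"]],
              min(x$sse)))
  invisible(x)
}

#' Sweep mutant expression levels through the twitch protocol
#'
#' Applies the full-expression mutation scalings at a series of expression
#' fractions (linear interpolation of `gamma` and `K_BC` between wild type
#' and mutant), simulates an averaged isometric twitch at each level, and
#' tabulates the twitch metrics and their percent changes relative to the
#' 0-expression (wild-type) row.
#'
#' @param wt wild-type [param_set()].
#' @param mutation a [mutation_spec()] describing 100% expression (its own
#'   `expression` field is ignored).
#' @param expressions fractions in `[0, 1]`; must include 0 (default 0 to 1
#'   in steps of 0.1).
#' @param transient,n_traj,n_repeats,seed,sample_dt,burn_in passed to
#'   [simulate_twitch()]; all expression levels share the same seeds so
#'   differences between rows reflect the parameters.
#' @param smooth_window low-pass window (seconds) applied by
#'   [twitch_metrics()] before metric extraction; averaged stochastic
#'   traces carry residual Monte-Carlo noise that otherwise destabilizes
#'   the threshold-crossing metrics (RT50 in particular).
#' @return A data frame of class `c("tf_expression_sweep", "data.frame")`
#'   with columns `expression`, `f_peak`, `ttp`, `rt50`, `nfti` and percent
#'   changes `pct_f_peak`, `pct_ttp`, `pct_rt50`, `pct_nfti`.
#' @export
expression_sweep <- function(wt, mutation = mutation_spec(),
                             expressions = seq(0, 1, by = 0.1),
                             transient = ca_transient(),
                             n_traj = 192L, n_repeats = 2L, seed = 1L,
                             sample_dt = 0.002, burn_in = 0.5,
                             smooth_window = 0.02) {
  stopifnot(inherits(wt, "tf_params"), inherits(mutation, "tf_mutation"))
  if (any(expressions < 0 | expressions > 1))
    stop("expressions must lie in [0, 1]")
  if (!any(expressions == 0))
    stop("expressions must include 0 (the wild-type reference)")
  expressions <- sort(unique(expressions))

  rows <- lapply(expressions, function(e) {
    spec <- mutation_spec(mutation$gamma_scale, mutation$kbc_scale, e)
    tw <- simulate_twitch(apply_mutation(wt, spec), transient,
                          n_traj = n_traj, n_repeats = n_repeats,
                          seed = seed, sample_dt = sample_dt,
                          burn_in = burn_in)
    m <- twitch_metrics(tw, smooth_window = smooth_window)
    data.frame(expression = e, f_peak = m$f_peak, ttp = m$ttp,
               rt50 = m$rt50, nfti = m$nfti)
  })
  out <- do.call(rbind, rows)
  ref <- out[out$expression == 0, ]
  for (v in c("f_peak", "ttp", "rt50", "nfti"))
    out[[paste0("pct_", v)]] <- 100 * (out[[v]] - ref[[v]]) / ref[[v]]
  class(out) <- c("tf_expression_sweep", "data.frame")
  out
}

#' Engineered-heart-tissue twitch-change targets
#'
#' Percent changes (mutant vs wild type) in peak force, RT50 and nFTI used
#' to infer the mutant expression level, with optional standard-error
#' half-widths defining an admissibility window per metric. Time to peak is
#' deliberately not part of the inference and is reported alongside for
#' completeness by [expression_sweep()].
#'
#' @param pct_f_peak,pct_rt50,pct_nfti percent changes.
#' @param sem optional named numeric vector of half-widths, names among
#'   `"pct_f_peak"`, `"pct_rt50"`, `"pct_nfti"`.
#' @return An object of class `tf_twitch_targets`.
#' @export
twitch_delta_targets <- function(pct_f_peak, pct_rt50, pct_nfti,
                                 sem = NULL) {
  v <- c(pct_f_peak = pct_f_peak, pct_rt50 = pct_rt50, pct_nfti = pct_nfti)
  stopifnot(all(is.finite(v)))
  if (!is.null(sem)) {
    if (is.null(names(sem)) || !all(names(sem) %in% names(v)))
      stop("sem must be named with metrics among ", paste(names(v),
                                                          collapse = ", "))
    stopifnot(all(sem >= 0))
  }
  structure(list(targets = v, sem = sem), class = "tf_twitch_targets")
}

#' Infer mutant expression from twitch-change targets
#'
#' Finds the expression level whose predicted percent changes in peak
#' force, RT50 and nFTI best match the measured targets (minimum
#' equally-weighted sum of squared differences across the three metrics).
#' If standard-error half-widths are supplied, also returns the admissible
#' set: the sweep expressions at which every prediction falls inside its
#' `mean +/- sem` window. An empty admissible set is flagged, not an error.
#'
#' @param sweep an [expression_sweep()] result (at least 3 expression
#'   levels).
#' @param targets a [twitch_delta_targets()].
#' @return An object of class `tf_expression_match`: list with
#'   `best_expression`, `sse` (per sweep row), `admissible` (expression
#'   values, possibly empty), and `admissible_empty` flag.
#' @export
infer_expression <- function(sweep, targets) {
  stopifnot(inherits(sweep, "tf_expression_sweep"),
            inherits(targets, "tf_twitch_targets"))
  if (nrow(sweep) < 3L) stop("sweep needs at least 3 expression levels")
  metrics <- names(targets$targets)
  pred <- as.matrix(sweep[, metrics])
  err <- pred - matrix(targets$targets, nrow(pred), ncol(pred), byrow = TRUE)
  sse <- rowSums(err^2)
  best <- sweep$expression[which.min(sse)]

  admissible <- numeric(0)
  if (!is.null(targets$sem)) {
    ok <- rep(TRUE, nrow(sweep))
    for (m in names(targets$sem))
      ok <- ok & abs(pred[, m] - targets$targets[[m]]) <= targets$sem[[m]]
    admissible <- sweep$expression[ok]
  }
  structure(list(best_expression = best, sse = sse,
                 admissible = admissible,
                 admissible_empty = !is.null(targets$sem) &&
                   length(admissible) == 0L),
            class = "tf_expression_match")
}

#' @export
print.tf_expression_match <- function(x, ...) {
  cat(sprintf("Best-match expression: %.0f%%\n", 100 * x$best_expression))
  if (length(x$admissible))
    cat("  admissible window:",
        paste0(100 * range(x$admissible), "%", collapse = " - "), "\n")
  else if (x$admissible_empty)
    cat("  admissible window: empty (no expression satisfies all SEM",
        "bounds)\n")
  invisible(x)
}

#' Bootstrap comparison of two metric groups
#'
#' Percentile bootstrap of the difference in group means (`group_a` minus
#' `group_b`), with a two-sided p-value estimated from the fraction of
#' resampled differences on the far side of zero. Deterministic given
#' `seed`. Degenerate input (both groups constant and equal) yields a
#' zero-width interval and a flagged (`NA`) p-value.
#'
#' @param group_a,group_b numeric vectors, each of length >= 3.
#' @param n_resamples bootstrap resamples (default 10,000).
#' @param seed integer seed.
#' @param conf confidence level for the percentile interval.
#' @return A list with `mean_diff`, `ci` (length-2), `p_value`,
#'   `n_resamples`, `degenerate`.
#' @export
bootstrap_compare <- function(group_a, group_b, n_resamples = 10000L,
                              seed = 1L, conf = 0.95) {
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("each group needs at least 3 values")
  stopifnot(all(is.finite(group_a)), all(is.finite(group_b)))
  obs <- mean(group_a) - mean(group_b)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  na <- length(group_a); nb <- length(group_b)
  diffs <- vapply(seq_len(n_resamples), function(i)
    mean(group_a[sample.int(na, na, replace = TRUE)]) -
      mean(group_b[sample.int(nb, nb, replace = TRUE)]),
    numeric(1))

  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(diffs, c(alpha, 1 - alpha), type = 7))
  degenerate <- stats::sd(c(group_a, group_b)) == 0
  p <- if (degenerate) NA_real_ else
    min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  list(mean_diff = obs, ci = ci, p_value = p,
       n_resamples = as.integer(n_resamples), degenerate = degenerate)
}
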