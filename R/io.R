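# Readers/writers and the reproducible pipeline driver.

#' Read a parameter set from a config file
#'
#' Reads a flat key-value file (JSON, or YAML when the file extension is
#' `.yaml`/`.yml` and the yaml package is available) whose keys match the
#' model symbol names (`kCa_plus`, ..., `K_BC`, `f_XY`, `delta`, `lam`,
#' `eta`, `mu`, `gamma`, optionally `n_units` and `rt`).
#'
#' @param path file path.
#' @return A [param_set()].
#' @export
read_param_set <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML parameter files")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  missing <- setdiff(PARAM_FIELDS, names(vals))
  if (length(missing))
    stop("parameter file is missing: ", paste(missing, collapse = ", "))
  do.call(param_set, c(vals[PARAM_FIELDS],
                       list(n_units = vals$n_units %||% 26L,
                            rt = vals$rt %||% RT_DEFAULT)))
}

#' Write a parameter set to a config file
#'
#' @param params a [param_set()].
#' @param path destination; `.json` (default) or `.yaml`/`.yml`.
#' @return `path`, invisibly.
#' @export
write_param_set <- function(params, path) {
  stopifnot(inherits(params, "tf_params"))
  vals <- params[c(PARAM_FIELDS, "n_units", "rt")]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to write YAML parameter files")
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write a force trace (or any tabular result) as CSV
#'
#' @param x a data frame, [simulate_twitch()] trace or
#'   [simulate_ensemble()] result (converted via `as.data.frame`).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a force trace CSV written by [write_trace_csv()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  utils::read.csv(path)
}

pipeline_stages <- c("gen_synthetic", "simulate_pca", "simulate_twitch",
                     "fit_ivma", "expression_sweep", "infer_expression")

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order -- steady-state sweep
#' and Hill fit, twitch simulation and metrics, mutant grid search against
#' motility targets, expression sweep, and expression inference from twitch
#' targets -- writing each stage's artifacts (CSV tables, JSON metrics)
#' under `out_dir` and a run manifest (`manifest.json`) recording the
#' configuration snapshot, parameter-set provenance, seeds, package version
#' and every artifact path. Deterministic stages reproduce bit-identical
#' artifacts when re-run from the same configuration. Existing artifacts
#' are reused when `config$resume` is `TRUE`; a stage whose upstream
#' artifact is absent raises a dependency error.
#'
#' @param config a named list (or path to a JSON/YAML file) with elements:
#'   `stages` (subset of `"gen_synthetic"`, `"simulate_pca"`,
#'   `"simulate_twitch"`, `"fit_ivma"`, `"expression_sweep"`,
#'   `"infer_expression"`),
#'   `param_set` (`"set1"`, `"set2"` or a parameter-file path),
#'   `seed`, `n_traj`, and optional stage-specific entries:
#'   `ivma_targets` (list `delta_pca50`, `pct_delta_vmax`),
#'   `twitch_targets` (list `pct_f_peak`, `pct_rt50`, `pct_nfti`, optional
#'   `sem`), `mutation` (list `gamma_scale`, `kbc_scale`), `expressions`,
#'   `pca_grid`, `gamma_scales`, `kbc_scales`, `n_repeats`, `duration`,
#'   `window`, `resume`.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config, out_dir = "thinfil-run") {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the yaml package is required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  stages <- match.arg(config$stages %||% "simulate_pca", pipeline_stages,
                      several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]  # dependency order
  seed <- as.integer(config$seed %||% 1L)
  n_traj <- as.integer(config$n_traj %||% 120L)
  resume <- isTRUE(config$resume)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  prov <- config$param_set %||% "set1"
  params <- if (prov %in% c("set1", "set2")) thinfil_params(prov)
            else read_param_set(prov)
  mut_cfg <- config$mutation %||% list(gamma_scale = 0.5, kbc_scale = 0.74)
  mutation <- mutation_spec(mut_cfg$gamma_scale, mut_cfg$kbc_scale, 1)

  artifacts <- list()
  log_lines <- character(0)
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  path_of <- function(name) file.path(out_dir, name)
  fresh <- function(name) !(resume && file.exists(path_of(name)))

  if ("gen_synthetic" %in% stages) {
    if (fresh("synthetic_ivma.csv")) {
      pts <- gen_ivma_points(noise_sd = config$noise_sd %||% 0.02,
                             seed = seed)
      utils::write.csv(pts, path_of("synthetic_ivma.csv"), row.names = FALSE)
    }
    if (fresh("synthetic_twitch.csv")) {
      tw <- gen_twitch_trace(noise_sd = config$noise_sd %||% 0.02,
                             seed = seed + 1L)
      utils::write.csv(tw, path_of("synthetic_twitch.csv"),
                       row.names = FALSE)
    }
    artifacts$synthetic_ivma <- path_of("synthetic_ivma.csv")
    artifacts$synthetic_twitch <- path_of("synthetic_twitch.csv")
    note("gen_synthetic", "wrote synthetic IVMA points and twitch trace")
  }

  if ("simulate_pca" %in% stages) {
    if (fresh("pca_sweep.csv")) {
      sw <- run_pca_sweep(params,
                          pca_grid = config$pca_grid %||%
                            seq(7.0, 4.5, length.out = 21),
                          n_traj = n_traj, seed = seed,
                          duration = config$duration %||% 10,
                          window = config$window %||% c(7.5, 10))
      utils::write.csv(sw, path_of("pca_sweep.csv"), row.names = FALSE)
      fit <- fit_hill(sw[, c("pca", "force")])
      jsonlite::write_json(fit[c("f_max", "pca50", "n_h", "residual_sse")],
                           path_of("hill_fit.json"), auto_unbox = TRUE,
                           digits = NA)
    }
    artifacts$pca_sweep <- path_of("pca_sweep.csv")
    artifacts$hill_fit <- path_of("hill_fit.json")
    note("simulate_pca", "steady-state sweep + Hill fit")
  }

  if ("simulate_twitch" %in% stages) {
    if (fresh("twitch.csv")) {
      tw <- simulate_twitch(params, n_traj = n_traj,
                            n_repeats = as.integer(config$n_repeats %||% 2L),
                            seed = seed)
      write_trace_csv(tw, path_of("twitch.csv"))
      m <- twitch_metrics(tw)
      jsonlite::write_json(m[c("f_peak", "ttp", "rt50", "nfti")],
                           path_of("twitch_metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    artifacts$twitch <- path_of("twitch.csv")
    artifacts$twitch_metrics <- path_of("twitch_metrics.json")
    note("simulate_twitch", "averaged twitch + metrics")
  }

  if ("fit_ivma" %in% stages) {
    tcfg <- config$ivma_targets
    if (is.null(tcfg))
      stop("stage fit_ivma requires config$ivma_targets ",
           "(delta_pca50, pct_delta_vmax)")
    if (fresh("sse_surface.csv")) {
      gs <- grid_search_ivma(
        params,
        gamma_scales = config$gamma_scales %||% seq(0.1, 1, length.out = 10),
        kbc_scales = config$kbc_scales %||% seq(0.55, 1, length.out = 10),
        targets = ivma_targets(tcfg$delta_pca50, tcfg$pct_delta_vmax),
        pca_grid = config$pca_grid %||% seq(7.0, 4.5, length.out = 13),
        n_traj = n_traj, seed = seed)
      long <- gs$cells
      long$sse <- as.vector(gs$sse)
      utils::write.csv(long, path_of("sse_surface.csv"), row.names = FALSE)
      jsonlite::write_json(as.list(gs$argmin), path_of("ivma_argmin.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    artifacts$sse_surface <- path_of("sse_surface.csv")
    artifacts$ivma_argmin <- path_of("ivma_argmin.json")
    note("fit_ivma", "grid search over gamma/K_BC scalings")
  }

  if ("expression_sweep" %in% stages) {
    if (fresh("expression_sweep.csv")) {
      sw <- expression_sweep(params, mutation,
                             expressions = config$expressions %||%
                               seq(0, 1, by = 0.1),
                             n_traj = n_traj,
                             n_repeats = as.integer(config$n_repeats %||%
                                                      2L),
                             seed = seed)
      utils::write.csv(sw, path_of("expression_sweep.csv"),
                       row.names = FALSE)
    }
    artifacts$expression_sweep <- path_of("expression_sweep.csv")
    note("expression_sweep", "twitch metrics across expression levels")
  }

  if ("infer_expression" %in% stages) {
    sweep_path <- path_of("expression_sweep.csv")
    if (!file.exists(sweep_path))
      stop("stage infer_expression requires the expression_sweep artifact (",
           sweep_path, "); run the expression_sweep stage first")
    tcfg <- config$twitch_targets
    if (is.null(tcfg))
      stop("stage infer_expression requires config$twitch_targets ",
           "(pct_f_peak, pct_rt50, pct_nfti)")
    sw <- utils::read.csv(sweep_path)
    class(sw) <- c("tf_expression_sweep", "data.frame")
    targ <- twitch_delta_targets(tcfg$pct_f_peak, tcfg$pct_rt50,
                                 tcfg$pct_nfti,
                                 sem = unlist(tcfg$sem %||% NULL))
    em <- infer_expression(sw, targ)
    jsonlite::write_json(
      list(best_expression = em$best_expression,
           admissible = em$admissible,
           admissible_empty = em$admissible_empty),
      path_of("expression_match.json"), auto_unbox = TRUE, digits = NA)
    artifacts$expression_match <- path_of("expression_match.json")
    note("infer_expression",
         sprintf("best-match expression %.0f%%",
                 100 * em$best_expression))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("thinfil")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    param_set_provenance = prov,
    seed = seed,
    n_traj = n_traj,
    stages = stages,
    artifacts = artifacts,
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(manifest)
}
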