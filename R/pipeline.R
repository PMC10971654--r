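# End-to-end pipeline: configuration files, simulate / analyze / report.
# These functions are the programmatic face of the command-line tool in
# inst/cli/gard.R; each is idempotent given identical inputs and seeds.

#' Read a run configuration file
#'
#' YAML or JSON (decided by extension). Recognized fields: `pi`, `k_fwd`,
#' `k_bwd`, `beta` (either a spec block with `kind` and its parameters, or a
#' `path` to a delimited matrix), `n_assemblies`, `split_size`,
#' `n_generations`, `seed`, `kinetics_mode`, `rate_form`, `walk` (`M`,
#' `N_rw`, `N`, `molar`), `k`, `eta`, `epsilon`, `shifts` (list of
#' `trigger_generation` / `new_pi` blocks). Missing analysis fields fall
#' back to package defaults.
#'
#' @param path Config file path.
#' @return A validated run configuration (list), as produced by
#'   [build_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  build_run_config(raw)
}

#' Validate a raw configuration list
#'
#' @param raw Named list of configuration fields (see [read_run_config()]).
#' @return List with components `env`, `beta`, `config`, `walk`, `shifts`,
#'   `k`, `eta`, `epsilon`.
#' @export
build_run_config <- function(raw) {
  need <- function(field) {
    if (is.null(raw[[field]])) {
      stop("config field '", field, "' is required", call. = FALSE)
    }
    raw[[field]]
  }
  env <- gard_environment(need("pi"),
                          k_fwd = raw$k_fwd %||% 1,
                          k_bwd = raw$k_bwd %||% 0.2)
  b <- need("beta")
  beta <- if (!is.null(b$path) && is.null(b$kind)) {
    read_beta_matrix(b$path)
  } else {
    spec <- beta_spec(kind = b$kind %||% "lognormal_random",
                      mu = b$mu %||% -4, sigma = b$sigma %||% 4,
                      n_attractors = b$n_attractors %||% 2,
                      attractor_strength = b$attractor_strength %||% 10,
                      attractor_width = b$attractor_width %||% 3,
                      background = b$background %||% 0,
                      cross_strength = b$cross_strength %||% 0,
                      path = b$path, seed = b$seed %||% raw$seed %||% 1L)
    sample_beta(spec, env$n_types)
  }
  cfg <- reactor_config(need("n_assemblies"), need("split_size"),
                        need("n_generations"),
                        seed = raw$seed %||% 1L,
                        kinetics_mode = raw$kinetics_mode %||% "stochastic",
                        rate_form = raw$rate_form %||% "factor_on_net",
                        euler_dt = raw$euler_dt %||% 0.01)
  w <- raw$walk %||% list()
  walk <- walk_params(M = w$M %||% 10,
                      N_rw = w$N_rw %||% gard_constants$N_A,
                      N = w$N %||% (cfg$split_size * 0.75),
                      molar = w$molar %||% TRUE)
  shifts <- lapply(raw$shifts %||% list(), function(s)
    environment_shift(s$trigger_generation, s$new_pi))
  list(env = env, beta = beta, config = cfg, walk = walk, shifts = shifts,
       k = raw$k %||% 3L, eta = raw$eta %||% 0.9,
       epsilon = raw$epsilon %||% 0.01)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a GARD run and write its trajectory
#'
#' Runs the constant-population reactor from a preset name or a run
#' configuration and writes `trajectory.csv` plus its JSON sidecar to
#' `out_dir`.
#'
#' @param preset A preset name (see [gard_preset()]); mutually exclusive
#'   with `config`.
#' @param config A run configuration from [read_run_config()] /
#'   [build_run_config()] or a config file path.
#' @param seed Optional seed override.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `trajectory` and the written `path`.
#' @export
gard_simulate <- function(preset = NULL, config = NULL, seed = NULL,
                          out_dir = ".", quiet = FALSE) {
  if (is.null(preset) == is.null(config)) {
    stop("supply exactly one of `preset` or `config`", call. = FALSE)
  }
  if (!is.null(preset)) {
    run <- gard_preset(preset, seed = seed %||% 1L)
  } else {
    if (is.character(config)) config <- read_run_config(config)
    run <- config
    if (!is.null(seed)) run$config$seed <- as.integer(seed)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!quiet) {
    message("simulating ", run$config$n_generations, " growth-split events",
            " (population ", run$config$n_assemblies, ", seed ",
            run$config$seed, ")")
  }
  tr <- run_reactor(run$env, run$beta, run$config, run$shifts,
                    progress = if (quiet) 0 else 1000)
  path <- file.path(out_dir, "trajectory.csv")
  write_trajectory(tr, path)
  if (!quiet) message("wrote ", path)
  invisible(list(trajectory = tr, path = path, run = run))
}

#' Analyze a trajectory: compotypes, metrics, order-complexity diagram
#'
#' Clusters composomes into compotypes, computes the order/complexity time
#' series, and writes `compotypes.csv` (+ `compotypes_centroids.csv`),
#' `metrics.csv` and `diagram.csv` (columns `c`, `order`, `t`, ordered by
#' `t`) to `out_dir`.
#'
#' @param trajectory A `gard_trajectory` or a trajectory CSV path.
#' @param out_dir Output directory.
#' @param k,eta Clustering parameters (see [cluster_compotypes()]).
#' @param walk A [walk_params()]; by default M = 10, N = the trajectory's
#'   mean assembly size, N_rw = Avogadro's number, molar units.
#' @param epsilon Participation threshold for effective repertoires.
#' @param per_micelle Use the per-micelle indexing convention for the
#'   metrics (every assembly its own population) instead of the compotype
#'   convention.
#' @param seed Clustering seed.
#' @param quiet Suppress messages.
#' @return Invisibly, list with `series`, `metrics` and the written paths.
#' @export
gard_analyze <- function(trajectory, out_dir = ".", k = 3, eta = 0.9,
                         walk = NULL, epsilon = 0.01, per_micelle = FALSE,
                         seed = 1L, quiet = FALSE) {
  if (is.character(trajectory)) trajectory <- read_trajectory(trajectory)
  stopifnot(inherits(trajectory, "gard_trajectory"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ncols <- paste0("n_", seq_len(trajectory$n_types))
  if (is.null(walk)) {
    mean_size <- mean(rowSums(trajectory$records[, ncols]))
    walk <- walk_params(M = 10, N_rw = gard_constants$N_A, N = mean_size,
                        molar = TRUE)
  }
  series <- cluster_compotypes(trajectory, k = k, eta = eta, seed = seed)
  metrics <- if (per_micelle) {
    metrics_timeseries(trajectory, walk, epsilon = epsilon)
  } else {
    metrics_timeseries(series, walk, epsilon = epsilon)
  }
  p_series <- file.path(out_dir, "compotypes.csv")
  write_compotype_series(series, p_series)
  p_metrics <- file.path(out_dir, "metrics.csv")
  write_metrics(metrics, p_metrics, molar = walk$molar)
  diagram <- metrics[order(metrics$t), c("c", "order", "t")]
  p_diagram <- file.path(out_dir, "diagram.csv")
  utils::write.csv(diagram, p_diagram, row.names = FALSE)
  if (!quiet) {
    message("wrote ", p_series, ", ", p_metrics, ", ", p_diagram)
  }
  invisible(list(series = series, metrics = metrics,
                 paths = c(compotypes = p_series, metrics = p_metrics,
                           diagram = p_diagram)))
}

#' Summarize an order-complexity run
#'
#' Between the first and last generation of a metrics table: the percent
#' change in complexity, the percent change in order, and the entropy change
#' `S_r(end) - S_r(start)` in the table's units.
#'
#' @param metrics A metrics data frame or a metrics CSV path.
#' @param out Optional JSON output path.
#' @return List with `complexity_change_pct`, `order_change_pct`,
#'   `delta_S_r`, and the endpoint values.
#' @export
gard_report <- function(metrics, out = NULL) {
  if (is.character(metrics)) metrics <- read_metrics(metrics)
  if (nrow(metrics) < 2) {
    stop("metrics must have at least 2 rows", call. = FALSE)
  }
  first <- metrics[1, ]
  last <- metrics[nrow(metrics), ]
  rep <- list(
    complexity_change_pct = if (first$c > 0)
      100 * (last$c - first$c) / first$c else NA_real_,
    order_change_pct = 100 * (last$order - first$order) / first$order,
    delta_S_r = last$S_r - first$S_r,
    S_r_start = first$S_r, S_r_end = last$S_r,
    order_start = first$order, order_end = last$order,
    c_start = first$c, c_end = last$c,
    n_generations = nrow(metrics)
  )
  if (!is.null(out)) {
    jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  rep
}

#' List the available scenario presets
#'
#' @return Character vector of preset names.
#' @export
preset_list <- function() {
  c("slow_takeover", "rapid_takeover", "env_shift")
}
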