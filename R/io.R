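# Reading and writing the package's file formats: headerless delimited beta
# matrices, trajectory CSVs with JSON sidecars, compotype and metrics CSVs.

#' Read a catalytic matrix from a delimited text file
#'
#' Expects N_G rows by N_G columns of nonnegative numbers, no header; comma,
#' tab or whitespace separated (auto-detected). Row i holds the enhancement
#' of type i's accretion, column j the catalyzing type.
#'
#' @param path File path.
#' @return A validated [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("beta matrix file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- tryCatch(
    as.matrix(utils::read.table(path, header = FALSE, sep = sep)),
    error = function(e) stop("malformed beta matrix file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.numeric(m)) {
    stop("malformed beta matrix file '", path, "': non-numeric entries",
         call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop("beta matrix file '", path, "' is not square: ", nrow(m), "x",
         ncol(m), call. = FALSE)
  }
  beta_matrix(m)
}

#' Write a catalytic matrix as headerless CSV
#'
#' @param beta Square matrix.
#' @param path Output path.
#' @export
write_beta_matrix <- function(beta, path) {
  utils::write.table(unclass(beta), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

serialize_config <- function(trajectory) {
  cfg <- trajectory$config
  list(
    seed = cfg$seed,
    n_assemblies = cfg$n_assemblies,
    split_size = cfg$split_size,
    n_generations = cfg$n_generations,
    kinetics_mode = cfg$kinetics_mode,
    rate_form = cfg$rate_form,
    euler_dt = cfg$euler_dt,
    n_types = trajectory$n_types,
    pi = trajectory$env$pi,
    k_fwd = trajectory$env$k_fwd,
    k_bwd = trajectory$env$k_bwd,
    shifts = lapply(trajectory$shifts, function(s)
      list(trigger_generation = s$trigger_generation, new_pi = s$new_pi))
  )
}

config_hash <- function(config_list) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config_list, auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Write a trajectory CSV with its JSON sidecar
#'
#' One row per (generation, assembly) with columns `t`, `assembly_id`,
#' `parent_id`, `n_1` ... `n_NG`; the sidecar (`<path>.json`) stores the
#' full configuration, environment, shift schedule, seed and a config hash.
#'
#' @param trajectory A `gard_trajectory`.
#' @param path Output CSV path.
#' @return The CSV path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory$records, path, row.names = FALSE)
  cfg <- serialize_config(trajectory)
  cfg$config_hash <- config_hash(cfg)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path Trajectory CSV path; the sidecar `<path>.json` must exist
#'   alongside it.
#' @return A `gard_trajectory`.
#' @export
read_trajectory <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("trajectory file not found: ", path,
                               call. = FALSE)
  if (!file.exists(sidecar)) stop("trajectory sidecar not found: ", sidecar,
                                  call. = FALSE)
  records <- utils::read.csv(path)
  if (nrow(records) == 0) stop("trajectory file '", path, "' is empty",
                               call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  env <- gard_environment(meta$pi, meta$k_fwd, meta$k_bwd)
  cfg <- reactor_config(meta$n_assemblies, meta$split_size,
                        meta$n_generations, meta$seed, meta$kinetics_mode,
                        meta$rate_form, meta$euler_dt)
  shifts <- list()
  env_schedule <- list(list(from = 1L, pi = env$pi))
  if (length(meta$shifts)) {
    sh <- meta$shifts
    if (is.data.frame(sh)) {
      sh <- lapply(seq_len(nrow(sh)), function(i)
        list(trigger_generation = sh$trigger_generation[i],
             new_pi = unlist(sh$new_pi[i])))
    }
    for (s in sh) {
      shifts[[length(shifts) + 1L]] <-
        environment_shift(s$trigger_generation, s$new_pi)
      env_schedule[[length(env_schedule) + 1L]] <-
        list(from = as.integer(s$trigger_generation),
             pi = as.numeric(s$new_pi))
    }
  }
  structure(
    list(records = records, env = env, shifts = shifts, config = cfg,
         env_schedule = env_schedule, n_types = meta$n_types),
    class = "gard_trajectory"
  )
}

#' Write a compotype series to CSV
#'
#' The fractions table gets columns `t`, `P_1` ... `P_K`, `drift`; centroids
#' go to a companion file with columns `k`, `p_1` ... `p_NG`, `N_k`.
#'
#' @param series A `gard_compotype_series`.
#' @param path Fractions CSV path.
#' @param centroids_path Centroids CSV path (default `<path>` with a
#'   `_centroids` suffix).
#' @return `path`, invisibly.
#' @export
write_compotype_series <- function(series, path,
                                   centroids_path = NULL) {
  if (is.null(centroids_path)) {
    centroids_path <- sub("(\\.[^.]*)?$", "_centroids\\1", path)
  }
  df <- data.frame(t = series$t)
  df <- cbind(df, as.data.frame(series$P))
  df$drift <- series$drift
  utils::write.csv(df, path, row.names = FALSE)
  cen <- data.frame(k = seq_len(series$k))
  prof <- as.data.frame(series$profiles)
  names(prof) <- paste0("p_", seq_len(ncol(prof)))
  cen <- cbind(cen, prof)
  cen$N_k <- series$N_k
  utils::write.csv(cen, centroids_path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics table to CSV
#'
#' A leading comment line documents the units (per-walk vs molar).
#'
#' @param metrics Data frame from [metrics_timeseries()].
#' @param path Output path.
#' @param molar Whether the values are molar (controls the unit comment).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, molar = FALSE) {
  units <- if (molar) {
    "# units: S_r in J/(K*mol), order in K*mol/J, c in bit/mol"
  } else {
    "# units: S_r in J/K per walk, order in K/J, c in bit per walk"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(units, con)
  utils::write.csv(metrics, con, row.names = FALSE)
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics()]
#'
#' @param path Metrics CSV path.
#' @return Data frame of metrics.
#' @export
read_metrics <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
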