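# Shared fixtures: tiny environments, matrices and hand-built trajectories.

uniform_env <- function(n, k_fwd = 1, k_bwd = 0.2) {
  gard_environment(rep(1 / n, n), k_fwd = k_fwd, k_bwd = k_bwd)
}

zero_beta <- function(n) matrix(0, n, n)

# A hand-built trajectory object whose records are supplied directly; used
# to exercise the analysis layer on exactly known inputs.
fake_trajectory <- function(records, env, n_generations = max(records$t),
                            n_assemblies = sum(records$t == records$t[1])) {
  cfg <- reactor_config(n_assemblies, 60, n_generations, seed = 1L)
  structure(
    list(records = records, env = env, shifts = list(), config = cfg,
         env_schedule = list(list(from = 1L, pi = env$pi)),
         n_types = env$n_types),
    class = "gard_trajectory"
  )
}

# Records for a population that reproduces perfectly: every generation the
# single parent yields two progeny with identical proportions.
perfect_records <- function(counts, n_gen, n_pop = 2) {
  n <- length(counts)
  rows <- list()
  id <- n_pop
  ids <- seq_len(n_pop)
  parents <- rep(NA_integer_, n_pop)
  for (g in seq_len(n_gen)) {
    j <- 1L + (g - 1L) %% n_pop
    pid <- ids[j]
    ids[j] <- id + 1L
    e <- if (j == n_pop) 1L else j + 1L
    ids[e] <- id + 2L
    parents[j] <- pid
    parents[e] <- pid
    id <- id + 2L
    for (a in seq_len(n_pop)) {
      rows[[length(rows) + 1L]] <- data.frame(
        t = g, assembly_id = ids[a], parent_id = parents[a],
        as.data.frame(t(counts)))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[4:(3 + n)] <- paste0("n_", seq_len(n))
  out
}

# Independent enumeration oracle: number of compositions of n molecules
# over k types, by recursion (no closed form used).
count_compositions <- function(k, n) {
  if (k == 1) return(1)
  s <- 0
  for (first in 0:n) s <- s + count_compositions(k - 1, n - first)
  s
}

run_smooth <- function(x, w) gardsim:::runmean(x, w)
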