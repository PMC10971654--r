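# Constant-population growth-split reactor.
#
# The reactor holds a fixed number of assemblies. One growth-split event
# ("generation"): pick an assembly uniformly at random, grow it to the
# splitting size, split it into two progeny, keep both, and evict one
# uniformly chosen non-progeny assembly so the population stays constant
# (a Moran-type scheme). Every generation the full population composition
# is recorded, which is the time axis of all downstream analyses.

#' Reactor configuration
#'
#' @param n_assemblies Constant population size (>= 1).
#' @param split_size Assembly size triggering fission; even, >= 2.
#' @param n_generations Number of growth-split events to simulate.
#' @param seed Integer master seed; the whole trajectory is a deterministic
#'   function of the configuration and this seed.
#' @param kinetics_mode `"stochastic"` (kinetic Monte-Carlo, default) or
#'   `"deterministic_euler"` (mean-field rate law integrated with a fixed
#'   Euler step; compositions become real-valued and fission is an exact
#'   halving).
#' @param rate_form See [net_rates()].
#' @param euler_dt Euler time step for the deterministic mode.
#' @param max_events Per-growth iteration cap (see [grow_to_split()]).
#' @return An object of class `gard_reactor_config`.
#' @export
reactor_config <- function(n_assemblies, split_size, n_generations, seed = 1L,
                           kinetics_mode = c("stochastic", "deterministic_euler"),
                           rate_form = c("factor_on_net", "factor_on_backward"),
                           euler_dt = 0.01, max_events = 1e6) {
  kinetics_mode <- match.arg(kinetics_mode)
  rate_form <- match.arg(rate_form)
  if (n_assemblies < 1) stop("n_assemblies must be >= 1", call. = FALSE)
  if (split_size < 2 || split_size %% 2 != 0) {
    stop("split_size must be even and >= 2", call. = FALSE)
  }
  if (n_generations < 1) stop("n_generations must be >= 1", call. = FALSE)
  structure(
    list(n_assemblies = as.integer(n_assemblies),
         split_size = as.integer(split_size),
         n_generations = as.integer(n_generations),
         seed = as.integer(seed),
         kinetics_mode = kinetics_mode,
         rate_form = rate_form,
         euler_dt = euler_dt,
         max_events = max_events),
    class = "gard_reactor_config"
  )
}

#' A sudden change of the external amphiphile concentrations
#'
#' Describes an environmental perturbation: at the trigger generation the
#' external fraction vector is replaced, modelling a sudden concentration
#' change in the milieu. Rate constants are left untouched.
#'
#' @param trigger_generation Generation (1-based) at which the shift fires,
#'   before that generation's growth-split event.
#' @param new_pi Replacement fraction vector (sums to 1).
#' @return An object of class `gard_environment_shift`.
#' @export
environment_shift <- function(trigger_generation, new_pi) {
  new_pi <- as.numeric(new_pi)
  if (any(new_pi < 0) || abs(sum(new_pi) - 1) > 1e-12) {
    stop("new_pi must be nonnegative and sum to 1", call. = FALSE)
  }
  if (trigger_generation < 1) {
    stop("trigger_generation must be >= 1", call. = FALSE)
  }
  structure(list(trigger_generation = as.integer(trigger_generation),
                 new_pi = new_pi),
            class = "gard_environment_shift")
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Run the constant-population growth-split reactor
#'
#' @param env A [gard_environment()]; `env$pi` may be replaced mid-run by
#'   entries of `shifts`.
#' @param beta Catalytic matrix.
#' @param cfg A [reactor_config()].
#' @param shifts Optional list of [environment_shift()] objects.
#' @param progress Print a progress line every `progress` generations
#'   (0, the default, is silent).
#' @return A `gard_trajectory`: list with `records` (data frame with columns
#'   `t`, `assembly_id`, `parent_id`, `n_1` ... `n_NG`; one row per standing
#'   assembly per generation), `env` (initial environment), `shifts`,
#'   `config`, and `env_schedule` (the pi vector in force from each
#'   generation onward).
#' @examples
#' env <- gard_environment(rep(0.25, 4))
#' cfg <- reactor_config(5, 20, 50, seed = 42)
#' tr <- run_reactor(env, matrix(0, 4, 4), cfg)
#' nrow(tr$records)  # 50 generations x 5 assemblies
#' @export
run_reactor <- function(env, beta, cfg, shifts = list(), progress = 0) {
  stopifnot(inherits(env, "gard_environment"),
            inherits(cfg, "gard_reactor_config"))
  beta <- beta_matrix(beta, env$n_types)
  if (inherits(shifts, "gard_environment_shift")) shifts <- list(shifts)
  for (s in shifts) {
    if (!inherits(s, "gard_environment_shift")) {
      stop("shifts must be environment_shift objects", call. = FALSE)
    }
    if (length(s$new_pi) != env$n_types) {
      stop("shift pi vector has wrong length", call. = FALSE)
    }
    if (s$trigger_generation > cfg$n_generations) {
      stop("shift trigger_generation ", s$trigger_generation,
           " exceeds n_generations", call. = FALSE)
    }
  }
  triggers <- vapply(shifts, function(s) s$trigger_generation, integer(1))
  if (anyDuplicated(triggers)) {
    stop("duplicate shift trigger generations", call. = FALSE)
  }

  nG <- env$n_types
  n_pop <- cfg$n_assemblies
  n_gen <- cfg$n_generations
  half <- cfg$split_size / 2
  deterministic <- cfg$kinetics_mode == "deterministic_euler"

  with_local_seed(cfg$seed, {
    # Seed population: multinomial draws at half the split size from pi.
    pop <- stats::rmultinom(n_pop, half, env$pi)
    storage.mode(pop) <- "double"
    ids <- seq_len(n_pop)
    parents <- rep(NA_integer_, n_pop)
    next_id <- n_pop + 1L

    rows <- n_gen * n_pop
    rec_t <- integer(rows)
    rec_id <- integer(rows)
    rec_parent <- integer(rows)
    rec_counts <- matrix(0, nrow = rows, ncol = nG)
    env_schedule <- list(list(from = 1L, pi = env$pi))
    cur_env <- env

    for (g in seq_len(n_gen)) {
      if (progress > 0 && g %% progress == 0) {
        message("generation ", g, "/", n_gen)
      }
      hit <- which(triggers == g)
      if (length(hit)) {
        cur_env$pi <- shifts[[hit]]$new_pi
        env_schedule[[length(env_schedule) + 1L]] <-
          list(from = g, pi = cur_env$pi)
      }
      j <- sample.int(n_pop, 1L)
      grown <- if (deterministic) {
        euler_grow_counts(pop[, j], cur_env, beta, cfg$split_size,
                          cfg$rate_form, cfg$euler_dt)
      } else {
        grow_to_split_counts(pop[, j], cur_env, beta, cfg$split_size,
                             cfg$rate_form, cfg$max_events)
      }
      first <- if (deterministic) grown / 2 else rmvhyper_half(grown)
      second <- grown - first
      pid <- ids[j]
      id1 <- next_id
      id2 <- next_id + 1L
      next_id <- next_id + 2L
      pop[, j] <- first
      ids[j] <- id1
      parents[j] <- pid
      if (n_pop > 1L) {
        e <- sample1(setdiff(seq_len(n_pop), j))
        pop[, e] <- second
        ids[e] <- id2
        parents[e] <- pid
      } else if (stats::runif(1) < 0.5) {
        # Population of one: only one progeny can survive.
        pop[, 1L] <- second
        ids[1L] <- id2
      }
      at <- ((g - 1L) * n_pop + 1L):(g * n_pop)
      rec_t[at] <- g
      rec_id[at] <- ids
      rec_parent[at] <- parents
      rec_counts[at, ] <- t(pop)
    }

    records <- data.frame(t = rec_t, assembly_id = rec_id,
                          parent_id = rec_parent)
    counts_df <- as.data.frame(rec_counts)
    names(counts_df) <- paste0("n_", seq_len(nG))
    records <- cbind(records, counts_df)

    structure(
      list(records = records, env = env, shifts = shifts, config = cfg,
           env_schedule = env_schedule, n_types = nG),
      class = "gard_trajectory"
    )
  })
}

#' @export
print.gard_trajectory <- function(x, ...) {
  cat("<gard_trajectory> ", x$config$n_generations, " generations x ",
      x$config$n_assemblies, " assemblies, ", x$n_types, " types\n", sep = "")
  invisible(x)
}

#' External fraction vector in force at a generation
#'
#' @param trajectory A `gard_trajectory`.
#' @param t Generation index.
#' @return The pi vector applying to generation `t`.
#' @export
env_at <- function(trajectory, t) {
  sched <- trajectory$env_schedule
  pi <- sched[[1]]$pi
  for (s in sched) if (s$from <= t) pi <- s$pi
  pi
}

# Matrix of per-type counts for one generation (assemblies in columns).
generation_counts <- function(trajectory, t) {
  rec <- trajectory$records
  rows <- rec$t == t
  t(as.matrix(rec[rows, paste0("n_", seq_len(trajectory$n_types))]))
}
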