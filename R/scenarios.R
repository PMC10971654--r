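# Synthetic generators and scenario presets.
#
# The beta matrices behind published GARD runs come from prior studies and
# are not reproduced here; instead this module samples random lognormal
# matrices (the conventional distribution for rate-enhancement factors) and
# builds engineered block-attractor matrices whose takeover behavior is
# controlled by construction: a block of mutually catalytic types forms a
# compositional attractor, and directed cross-catalysis (a later block's
# types catalyzed by an earlier block's members) opens a one-way conversion
# channel that produces takeovers at a tunable speed.

#' Specification of a catalytic matrix
#'
#' @param kind `"lognormal_random"`, `"engineered_attractors"` or
#'   `"from_file"`.
#' @param mu,sigma Log-space mean and sd for lognormal sampling. The default
#'   mu = -4, sigma = 4 follows the convention for sparse, heavy-tailed
#'   catalytic repertoires.
#' @param n_attractors Number of engineered attractor blocks.
#' @param attractor_strength Within-block enhancement factor; scalar or one
#'   value per block.
#' @param attractor_width Types per block; scalar or one per block.
#' @param background Enhancement factor outside the blocks.
#' @param cross_strength Catalysis of block b's types by members of block
#'   b - 1 (b >= 2); the takeover conversion channel. Scalar or length
#'   `n_attractors - 1`.
#' @param path Delimited matrix file for `kind = "from_file"`.
#' @param seed Sampling seed.
#' @return An object of class `gard_beta_spec`.
#' @export
beta_spec <- function(kind = c("lognormal_random", "engineered_attractors",
                               "from_file"),
                      mu = -4, sigma = 4,
                      n_attractors = 2, attractor_strength = 10,
                      attractor_width = 3, background = 0,
                      cross_strength = 0, path = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (any(attractor_strength <= 0) || any(attractor_width < 1) ||
      n_attractors < 1) {
    stop("attractor parameters must be positive", call. = FALSE)
  }
  if (kind == "from_file" && is.null(path)) {
    stop("kind = 'from_file' requires `path`", call. = FALSE)
  }
  structure(list(kind = kind, mu = mu, sigma = sigma,
                 n_attractors = as.integer(n_attractors),
                 attractor_strength = attractor_strength,
                 attractor_width = as.integer(attractor_width),
                 background = background, cross_strength = cross_strength,
                 path = path, seed = as.integer(seed)),
            class = "gard_beta_spec")
}

#' Sample or build a catalytic matrix
#'
#' @param spec A [beta_spec()].
#' @param n_types Matrix dimension N_G.
#' @return A validated [beta_matrix()]. Deterministic given `spec$seed`.
#' @export
sample_beta <- function(spec, n_types) {
  stopifnot(inherits(spec, "gard_beta_spec"))
  out <- switch(
    spec$kind,
    lognormal_random = with_local_seed(spec$seed, {
      matrix(stats::rlnorm(n_types^2, spec$mu, spec$sigma),
             n_types, n_types)
    }),
    engineered_attractors = {
      widths <- rep_len(spec$attractor_width, spec$n_attractors)
      strengths <- rep_len(spec$attractor_strength, spec$n_attractors)
      crosses <- rep_len(spec$cross_strength,
                         max(spec$n_attractors - 1L, 1L))
      if (sum(widths) > n_types) {
        stop("attractor blocks need ", sum(widths), " types but n_types is ",
             n_types, call. = FALSE)
      }
      beta <- matrix(spec$background, n_types, n_types)
      stops <- cumsum(widths)
      starts <- stops - widths + 1L
      for (b in seq_len(spec$n_attractors)) {
        blk <- starts[b]:stops[b]
        beta[blk, blk] <- strengths[b]
        if (b >= 2L && crosses[b - 1L] > 0) {
          beta[blk, starts[b - 1L]:stops[b - 1L]] <- crosses[b - 1L]
        }
      }
      beta
    },
    from_file = read_beta_matrix(spec$path)
  )
  beta_matrix(out, n_types)
}

#' Named scenario presets
#'
#' Full run configurations whose qualitative population dynamics are fixed
#' by construction. All three run a population of 100 assemblies splitting
#' at 60 molecules; the population size sets the takeover clock, since each
#' lineage reproduces once per `n_assemblies` growth-split events on
#' average.
#'
#' * `slow_takeover`: a broad, common, weakly catalytic attractor (types
#'   1-4) wins the initial commitment race; a rarer but much more strongly
#'   self-catalytic attractor (types 5-7) invades lineage by lineage through
#'   stochastic tipping, so dominance is exchanged gradually while the total
#'   composome fraction keeps rising.
#' * `rapid_takeover`: a narrow two-type attractor at high external
#'   concentration polarizes first (high order); a broad six-type attractor
#'   with very strong self-catalysis then converts the population within a
#'   short window. The total composome fraction passes an interior maximum
#'   (the narrow state reproduces more faithfully than its broad successor)
#'   and the order transiently drops while complexity still rises.
#' * `env_shift`: two equally strong three-type attractors whose commitment
#'   is decided by the external fractions; a sudden concentration change at
#'   mid-run reverses which attractor the influx supports, flipping the
#'   dominance ranking.
#'
#' @param name Preset name.
#' @param seed Master seed for the run.
#' @return List with components `env`, `beta_spec`, `beta`, `config`
#'   ([reactor_config()]), `walk` ([walk_params()]), `shifts`, `k`, `eta`,
#'   `epsilon` and `name`.
#' @export
gard_preset <- function(name = c("slow_takeover", "rapid_takeover",
                                 "env_shift"),
                        seed = 1L) {
  name <- match.arg(name)
  split_size <- 60L
  walk <- walk_params(M = 5, N_rw = gard_constants$N_A, N = split_size / 2,
                      molar = TRUE)
  preset <- switch(
    name,
    slow_takeover = {
      pi <- c(rep(0.10, 4), rep(0.05, 3), rep(0.15, 3))
      list(
        env = gard_environment(pi / sum(pi), k_fwd = 1, k_bwd = 0.1),
        spec = beta_spec("engineered_attractors", n_attractors = 2,
                         attractor_strength = c(18, 80),
                         attractor_width = c(4, 3),
                         background = 0.2),
        cfg = reactor_config(100, split_size, 4500, seed = seed),
        shifts = list(), k = 2L, eta = 0.95, epsilon = 0.01
      )
    },
    rapid_takeover = {
      pi <- c(rep(0.21, 2), rep(0.015, 6), rep(0.1225, 4))
      list(
        env = gard_environment(pi / sum(pi), k_fwd = 1, k_bwd = 0.05),
        spec = beta_spec("engineered_attractors", n_attractors = 2,
                         attractor_strength = c(30, 300),
                         attractor_width = c(2, 6),
                         background = 0.2),
        cfg = reactor_config(100, split_size, 4000, seed = seed),
        shifts = list(), k = 3L, eta = 0.95, epsilon = 0.10
      )
    },
    env_shift = {
      pi_a <- c(rep(0.055, 3), rep(0.145, 3), rep(0.10, 4))
      pi_b <- c(rep(0.145, 3), rep(0.055, 3), rep(0.10, 4))
      list(
        env = gard_environment(pi_a / sum(pi_a), k_fwd = 1, k_bwd = 0.1),
        spec = beta_spec("engineered_attractors", n_attractors = 2,
                         attractor_strength = c(50, 50),
                         attractor_width = c(3, 3),
                         background = 0.2),
        cfg = reactor_config(100, split_size, 4000, seed = seed),
        shifts = list(environment_shift(2000, pi_b / sum(pi_b))),
        k = 2L, eta = 0.95, epsilon = 0.01
      )
    }
  )
  nG <- preset$env$n_types
  beta <- sample_beta(preset$spec, nG)
  list(name = name, env = preset$env, beta_spec = preset$spec, beta = beta,
       config = preset$cfg, walk = walk, shifts = preset$shifts,
       k = preset$k, eta = preset$eta, epsilon = preset$epsilon)
}

#' Analytic compotype-series fixtures
#'
#' Closed-form P_k(t) curves with fixed compotype profiles, bypassing
#' simulation, for deterministic tests of the metric pipeline. Shapes:
#' `fig4_like` (gradual takeover, total composome fraction nondecreasing),
#' `fig6_like` (rapid takeover, total fraction with an interior maximum),
#' `fig8_like` (piecewise-constant environment with one switch and a
#' dominance reversal).
#'
#' @param shape Fixture shape.
#' @param n_generations Series length (>= 10).
#' @param n_types Repertoire size (default 20).
#' @return A `gard_compotype_series`.
#' @export
fixture_compotype_series <- function(shape = c("fig4_like", "fig6_like",
                                               "fig8_like"),
                                     n_generations = 2000, n_types = 20) {
  shape <- match.arg(shape)
  if (n_generations < 10) stop("n_generations must be >= 10", call. = FALSE)
  t <- seq_len(n_generations)
  Tn <- n_generations
  sig <- function(x) 1 / (1 + exp(-x))
  uniform <- rep(1 / n_types, n_types)
  env <- gard_environment(uniform)

  # Three profiles: permutations of one 4-type pattern, so all carry the
  # same per-molecule entropy (reallocating weight among them moves the
  # complexity but not the entropy balance).
  base_profile <- function(types) {
    p <- rep(0, n_types)
    p[types] <- c(0.4, 0.3, 0.2, 0.1)
    p
  }
  profiles <- rbind(base_profile(1:4), base_profile(5:8),
                    base_profile(9:12))
  N_k <- rep(30, 3)
  sched <- list(list(from = 1L, pi = uniform))

  if (shape == "fig4_like") {
    total <- 0.85 * sig((t - 0.2 * Tn) / (0.08 * Tn))
    P3 <- pmin(total, 0.55 * sig((t - 0.15 * Tn) / (0.05 * Tn))) *
      (1 - 0.6 * sig((t - 0.55 * Tn) / (0.1 * Tn)))
    P1 <- pmin(total - P3, 0.25 * sig((t - 0.3 * Tn) / (0.07 * Tn)))
    P2 <- total - P3 - P1
    P <- cbind(P1, P2, P3)
  } else if (shape == "fig6_like") {
    total <- 0.9 * sig((t - 0.1 * Tn) / (0.03 * Tn)) -
      0.2 * sig((t - 0.3 * Tn) / (0.08 * Tn))
    P3 <- pmin(total, 0.8 * sig((t - 0.08 * Tn) / (0.02 * Tn))) *
      (1 - 0.92 * sig((t - 0.25 * Tn) / (0.05 * Tn)))
    P1 <- pmin(total - P3, 0.2 * sig((t - 0.2 * Tn) / (0.05 * Tn)))
    P2 <- total - P3 - P1
    P <- cbind(P1, P2, P3)
  } else {
    halfway <- floor(Tn / 2)
    before <- t <= halfway
    P1 <- ifelse(before, 0.18 * sig((t - 0.1 * Tn) / (0.04 * Tn)),
                 0.18 + (0.55 - 0.18) * sig((t - halfway - 0.1 * Tn) /
                                              (0.04 * Tn)))
    P2 <- ifelse(before, 0.62 * sig((t - 0.1 * Tn) / (0.04 * Tn)),
                 0.62 - (0.62 - 0.40) * sig((t - halfway - 0.1 * Tn) /
                                              (0.04 * Tn)))
    P3 <- rep(0, Tn)
    P <- cbind(P1, P2, P3)
    shifted <- uniform * c(rep(1.4, 4), rep(0.6, 4), rep(1, n_types - 8))
    sched <- list(list(from = 1L, pi = uniform),
                  list(from = as.integer(halfway + 1L),
                       pi = shifted / sum(shifted)))
  }
  stopifnot(all(P >= -1e-12), all(rowSums(P) <= 1 + 1e-9))
  P[P < 0] <- 0
  colnames(P) <- paste0("P_", 1:3)
  rownames(profiles) <- paste0("compotype_", 1:3)
  structure(
    list(t = t, P = P, drift = 1 - rowSums(P), profiles = profiles,
         N_k = N_k, assignments = NULL, eta = NA_real_, k = 3L,
         weighting = "assemblies", env = env, env_schedule = sched),
    class = "gard_compotype_series"
  )
}
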