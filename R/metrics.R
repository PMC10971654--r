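# Order and complexity observables.
#
# Order: the reciprocal of the sequential entropy S_r assigned to the
# ensemble of virtual random walks through the system (aqueous monomers and
# micelles alternating). With H(q) = sum_i q_i ln(1/q_i),
#
#   S_r = k_B * [M*N_rw/(M+N)] * H(pi)
#       + k_B * sum_k P_k * [N_rw/(M+N)] * N_k * H(p_k)
#
# where M is the mean number of aqueous monomers between two micelles on the
# walk, N the mean micelle size, N_rw the total number of walk units, pi the
# external fractions, and (P_k, p_k, N_k) the population fraction, profile
# and mean size of micelle population k. Reporting molar quantities divides
# N_rw by Avogadro's number, i.e. S_r is expressed per mole of walk units in
# J/(K*mol) with R = k_B * N_A.
#
# Complexity: the code size needed to reproduce the walk statistics once
# composome attractors deviate from pi. Each compotype k drawing on an
# effective repertoire of N_Ck types over N_k molecules has
# multiset(N_Ck, N_k) possible compositions, and contributes
#
#   c_k = P_k * [N_rw/(M+N)] * log2 multiset(N_Ck, N_k)   (bits),
#
# summed over compotypes; micelles at the environment composition need no
# extra code and contribute nothing.

#' Random-walk parameters
#'
#' @param M Average number of aqueous monomers between two micelles on the
#'   walk (>= 0; may be `Inf` for a pure-monomer system).
#' @param N_rw Total number of units in the system and on the walk (>= 1).
#' @param N Average micelle size in molecules (>= 1).
#' @param molar If `TRUE`, entropies are reported per mole of walk units in
#'   J/(K*mol) (and complexities in bit/mol); otherwise per walk, in units of
#'   k_B (entropy) and bits (complexity).
#' @return An object of class `gard_walk_params`.
#' @export
walk_params <- function(M, N_rw, N, molar = FALSE) {
  if (M < 0) stop("M must be >= 0", call. = FALSE)
  if (N_rw < 1) stop("N_rw must be >= 1", call. = FALSE)
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  structure(list(M = M, N_rw = N_rw, N = N, molar = isTRUE(molar)),
            class = "gard_walk_params")
}

#' A population of micelle compositions
#'
#' Bundles the quantities entering the sequential entropy and complexity:
#' population fractions `P`, composition profiles (rows of `profiles`,
#' each summing to 1) and mean sizes `sizes`.
#'
#' @param P Numeric vector of population fractions, `sum(P) <= 1`.
#' @param profiles Matrix (length(P) x N_G) of composition fractions.
#' @param sizes Mean molecule number of each population.
#' @return An object of class `gard_population`.
#' @export
compotype_population <- function(P, profiles, sizes) {
  profiles <- rbind(profiles)
  if (length(P) != nrow(profiles) || length(sizes) != nrow(profiles)) {
    stop("P, profiles rows and sizes must agree in length", call. = FALSE)
  }
  if (any(P < 0) || sum(P) > 1 + 1e-9) {
    stop("P must be nonnegative with sum <= 1", call. = FALSE)
  }
  if (any(profiles < 0)) stop("profiles must be nonnegative", call. = FALSE)
  rs <- rowSums(profiles)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("each profile row must sum to 1", call. = FALSE)
  }
  if (any(sizes < 0)) stop("sizes must be >= 0", call. = FALSE)
  structure(list(P = as.numeric(P), profiles = unname(profiles),
                 sizes = as.numeric(sizes)),
            class = "gard_population")
}

# Shannon entropy in nats with the 0*log(0) = 0 convention.
nats <- function(q) {
  q <- q[q > 0]
  -sum(q * log(q))
}

# Complete a population with a drift component at the environment
# composition, so the walk can traverse non-composomal micelles too.
complete_population <- function(pop, env, walk, drift) {
  if (drift == "none") return(pop)
  rem <- 1 - sum(pop$P)
  if (rem <= 1e-12) return(pop)
  compotype_population(c(pop$P, rem),
                       rbind(pop$profiles, env$pi),
                       c(pop$sizes, walk$N))
}

#' Sequential entropy of the virtual random walks
#'
#' Evaluates the closed-form sequential entropy S_r of the walk ensemble for
#' a given micelle population, environment and walk geometry. `M = Inf`
#' gives the pure-monomer limit (the micelle term vanishes and every walk
#' unit is aqueous).
#'
#' @param population A [compotype_population()]; when `sum(P) < 1` and
#'   `drift = "environment"` the remainder is treated as micelles at the
#'   environment composition with mean size `walk$N`.
#' @param env A [gard_environment()].
#' @param walk A [walk_params()]; `walk$molar` selects the units.
#' @param drift `"environment"` (default) or `"none"`.
#' @return S_r, in J/K per walk (`molar = FALSE`) or J/(K*mol)
#'   (`molar = TRUE`). The attribute `w_log` carries ln of the statistical
#'   weight, i.e. S_r in units of k_B per walk.
#' @examples
#' env <- gard_environment(rep(1 / 20, 20))
#' pop <- compotype_population(1, matrix(1 / 20, 1, 20), 30)
#' wp <- walk_params(M = Inf, N_rw = 1e4, N = 30, molar = TRUE)
#' sequential_entropy(pop, env, wp)  # R * ln(20)
#' @export
sequential_entropy <- function(population, env, walk,
                               drift = c("environment", "none")) {
  drift <- match.arg(drift)
  stopifnot(inherits(population, "gard_population"),
            inherits(env, "gard_environment"),
            inherits(walk, "gard_walk_params"))
  if (ncol(population$profiles) != env$n_types) {
    stop("profile width must equal the number of amphiphile types",
         call. = FALSE)
  }
  pop <- complete_population(population, env, walk, drift)
  H_pi <- nats(env$pi)
  H_k <- apply(pop$profiles, 1, nats)
  if (is.infinite(walk$M)) {
    monomer_w <- walk$N_rw
    micelle_w <- 0
  } else {
    monomer_w <- walk$M * walk$N_rw / (walk$M + walk$N)
    micelle_w <- walk$N_rw / (walk$M + walk$N)
  }
  w_log <- monomer_w * H_pi + micelle_w * sum(pop$P * pop$sizes * H_k)
  # molar: per mole of walk units, (w_log / N_rw) * k_B * N_A = R * bracket
  s <- if (walk$molar) gard_constants$R * w_log / walk$N_rw else
    gard_constants$k_B * w_log
  structure(s, w_log = w_log)
}

#' Order of the system
#'
#' The reciprocal sequential entropy, `1 / S_r`: large when the walk
#' ensemble is narrowly determined (high compositional definition), small
#' for chaotic mixtures.
#'
#' @param S_r Sequential entropy (any consistent unit).
#' @return `1 / S_r`; `Inf` with a warning when `S_r == 0` (a perfectly
#'   ordered, degenerate system).
#' @export
order_value <- function(S_r) {
  S_r <- as.numeric(S_r)
  if (any(S_r < 0)) stop("S_r must be >= 0", call. = FALSE)
  if (any(S_r == 0)) {
    warning("S_r is 0: the system is perfectly ordered; returning Inf")
  }
  ifelse(S_r == 0, Inf, 1 / S_r)
}

#' Monte-Carlo sampler of walk strings
#'
#' Generates virtual walk strings by alternating aqueous stretches (`M`
#' draws from pi) with micelles (one population chosen with probability
#' `P_k`, contributing `N_k` draws from its profile), for
#' `round(N_rw / (M + N))` segments per walk, and returns the empirical mean
#' negative log-probability per walk in units of k_B -- the sampling
#' estimate of `S_r / k_B` that serves as an independent oracle for the
#' closed form.
#'
#' @inheritParams sequential_entropy
#' @param n_strings Number of walks to sample.
#' @param return_strings If `TRUE`, also return the sampled type-index
#'   strings (a list of integer vectors).
#' @return List with `entropy` (mean negative log-probability per walk, in
#'   k_B units), `se` (its Monte-Carlo standard error), `neg_log_prob` (the
#'   per-walk values) and optionally `strings`. Uses the current R random
#'   stream.
#' @export
sample_walk_string <- function(population, env, walk, n_strings = 1000,
                               drift = c("environment", "none"),
                               return_strings = FALSE) {
  drift <- match.arg(drift)
  stopifnot(inherits(population, "gard_population"),
            inherits(walk, "gard_walk_params"))
  if (is.infinite(walk$M)) {
    stop("the sampler requires finite M (use sequential_entropy for the ",
         "pure-monomer limit)", call. = FALSE)
  }
  pop <- complete_population(population, env, walk, drift)
  M <- as.integer(round(walk$M))
  n_seg <- max(1L, as.integer(round(walk$N_rw / (walk$M + walk$N))))
  K <- length(pop$P)
  sizes <- as.integer(round(pop$sizes))
  nlp_pi <- -log(env$pi)
  prof <- pop$profiles

  # Which population each segment's micelle belongs to, all walks at once.
  ks <- matrix(sample.int(K, n_strings * n_seg, replace = TRUE,
                          prob = pop$P), n_strings, n_seg)
  nlp <- numeric(n_strings)
  if (M > 0) {
    mono <- matrix(sample(nlp_pi, n_strings * n_seg * M, replace = TRUE,
                          prob = env$pi), n_strings)
    nlp <- rowSums(mono)
  }
  for (kk in seq_len(K)) {
    seg_count <- matrix(ks == kk, n_strings, n_seg)
    per_walk <- rowSums(seg_count) * sizes[kk]
    total <- sum(per_walk)
    if (total == 0) next
    p <- prof[kk, ]
    draws <- sample(-log(p[p > 0]), total, replace = TRUE, prob = p[p > 0])
    walk_of <- rep(seq_len(n_strings), per_walk)
    add <- rowsum(draws, walk_of)
    nlp[as.integer(rownames(add))] <- nlp[as.integer(rownames(add))] + add
  }

  out <- list(entropy = mean(nlp),
              se = stats::sd(nlp) / sqrt(n_strings),
              neg_log_prob = nlp)
  if (return_strings) {
    out$strings <- lapply(seq_len(n_strings), function(i) {
      s <- integer(0)
      for (j in seq_len(n_seg)) {
        if (M > 0) s <- c(s, sample.int(env$n_types, M, replace = TRUE,
                                        prob = env$pi))
        kk <- ks[i, j]
        if (sizes[kk] > 0)
          s <- c(s, sample.int(env$n_types, sizes[kk], replace = TRUE,
                               prob = prof[kk, ]))
      }
      s
    })
  }
  out
}

#' Compositional variability of a composome
#'
#' The number of distinct compositions of `N_k` molecules drawn from `N_Ck`
#' types: the multiset coefficient
#' \eqn{\binom{N_{Ck} + N_k - 1}{N_k}}, computed in log space so large
#' repertoires do not overflow.
#'
#' @param N_Ck Number of participating amphiphile types (>= 1).
#' @param N_k Number of molecules (>= 0; non-integer mean sizes are allowed
#'   and handled through the gamma function).
#' @param log2 If `TRUE`, return the base-2 logarithm of the coefficient.
#' @return The multiset coefficient (or its log2).
#' @examples
#' variability(3, 4)  # 15 compositions
#' @export
variability <- function(N_Ck, N_k, log2 = FALSE) {
  if (any(N_Ck < 1) || any(N_k < 0)) {
    stop("N_Ck must be >= 1 and N_k >= 0", call. = FALSE)
  }
  lg <- lchoose(N_Ck + N_k - 1, N_k)
  if (log2) return(lg / log(2))
  v <- exp(lg)
  ifelse(v < 2^53, round(v), v)
}

#' Effective repertoire of a compotype
#'
#' The number of amphiphile types materially participating in a compotype's
#' profile: types whose fraction exceeds `epsilon`. Types present only at
#' environment-level traces need no extra code and are not counted.
#'
#' @param p Normalized composition profile.
#' @param epsilon Participation threshold (default 0.01).
#' @return Integer count `N_Ck`, between 1 and `length(p)`.
#' @export
effective_repertoire <- function(p, epsilon = 0.01) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("profile must be nonnegative", call. = FALSE)
  n <- sum(p > epsilon)
  if (n == 0) {
    stop("no type exceeds the participation threshold; lower epsilon",
         call. = FALSE)
  }
  as.integer(n)
}

#' Kolmogorov-style complexity of the micelle population
#'
#' The code size, in bits, needed on top of a plain random generator to
#' reproduce the walk statistics: each compotype contributes
#' `P_k * N_rw/(M+N) * log2 variability(N_Ck, N_k)`.
#'
#' @inheritParams sequential_entropy
#' @param repertoires Integer vector of effective repertoire sizes `N_Ck`,
#'   one per population in `population`.
#' @return List with `c` (total complexity) and `c_k` (per-compotype
#'   contributions), in bits per walk, or bit/mol when `walk$molar`.
#' @export
complexity <- function(population, repertoires, walk) {
  stopifnot(inherits(population, "gard_population"),
            inherits(walk, "gard_walk_params"))
  if (length(repertoires) != length(population$P)) {
    stop("one repertoire size is required per population", call. = FALSE)
  }
  micelle_w <- if (is.infinite(walk$M)) 0 else
    walk$N_rw / (walk$M + walk$N)
  if (walk$molar) micelle_w <- micelle_w * gard_constants$N_A / walk$N_rw
  c_k <- population$P * micelle_w *
    variability(repertoires, population$sizes, log2 = TRUE)
  list(c = sum(c_k), c_k = c_k)
}

#' Binary enrichment/depletion code of a composome
#'
#' The simplest compositional information coding: one bit per amphiphile
#' type, 1 when the type is enriched (or unchanged) in the micelle relative
#' to the surrounding solution and 0 when depleted. A composome over N_G
#' types therefore carries N_G bits.
#'
#' @param p Composome profile (fractions).
#' @param pi External fractions, same length.
#' @return List with `codeword` (integer 0/1 vector) and `bits` (its
#'   length).
#' @examples
#' binary_information(c(0.4, 0.1, 0.5), c(1, 1, 1) / 3)
#' @export
binary_information <- function(p, pi) {
  p <- as.numeric(p); pi <- as.numeric(pi)
  if (length(p) != length(pi)) {
    stop("profile and environment fractions must have equal length",
         call. = FALSE)
  }
  codeword <- as.integer(p >= pi)
  list(codeword = codeword, bits = length(codeword))
}

#' Shortest RNA strand carrying a given information content
#'
#' A 4-letter alphabet carries 2 bits per base, so `bits` bits of
#' compositional information correspond to a strand of `ceiling(bits / 2)`
#' bases.
#'
#' @param bits Nonnegative information content in bits.
#' @return Number of bases.
#' @examples
#' rna_equivalent_length(20)  # 10
#' @export
rna_equivalent_length <- function(bits) {
  if (any(bits < 0)) stop("bits must be >= 0", call. = FALSE)
  ceiling(bits / 2)
}

#' Order and complexity along a trajectory or compotype series
#'
#' Applies [sequential_entropy()], [order_value()],
#' [effective_repertoire()] and [complexity()] at every generation.
#'
#' Two indexing conventions are supported. For a `gard_compotype_series`
#' (per-compotype): `k` runs over the clustered compotypes with their
#' fractions P_k(t), centroid profiles and mean sizes; drift micelles enter
#' the entropy at the environment composition and add no complexity. For a
#' `gard_trajectory` (per-micelle): `k` runs over individual assemblies with
#' P_k = 1/n_assemblies, each micelle's own fractions, and N_k equal to its
#' size (or 1 for every micelle when `unit_sizes = TRUE`).
#'
#' @param x A `gard_compotype_series` or `gard_trajectory`.
#' @param walk A [walk_params()].
#' @param env Environment; defaults to the one stored in `x` (per-generation
#'   shifts recorded in the series/trajectory are honored).
#' @param epsilon Participation threshold for the effective repertoire.
#' @param unit_sizes Per-micelle convention only: use N_k = 1 for all k.
#' @param ... Passed to methods.
#' @return Data frame with one row per generation: `t`, `S_r`, `order`, `c`,
#'   per-compotype `c_k` columns (compotype convention), and `order_rel`,
#'   `c_rel` (each scaled to its maximum over the series, the normalization
#'   used for relative-value time courses).
#' @export
metrics_timeseries <- function(x, walk, ...) UseMethod("metrics_timeseries")

#' @rdname metrics_timeseries
#' @export
metrics_timeseries.gard_compotype_series <- function(x, walk, env = NULL,
                                                     epsilon = 0.01, ...) {
  if (is.null(env)) env <- x$env
  k <- x$k
  reps <- vapply(seq_len(k), function(i)
    effective_repertoire(x$profiles[i, ], epsilon), integer(1))
  n_gen <- length(x$t)
  S_r <- numeric(n_gen)
  cc <- numeric(n_gen)
  c_k <- matrix(0, n_gen, k)
  cur_env <- env
  sched <- x$env_schedule
  for (g in seq_len(n_gen)) {
    if (!is.null(sched)) {
      for (s in sched) if (s$from == g) cur_env$pi <- s$pi
    }
    pop <- compotype_population(x$P[g, ], x$profiles, x$N_k)
    S_r[g] <- sequential_entropy(pop, cur_env, walk)
    cx <- complexity(pop, reps, walk)
    cc[g] <- cx$c
    c_k[g, ] <- cx$c_k
  }
  ord <- order_value(S_r)
  out <- data.frame(t = x$t, S_r = S_r, order = ord, c = cc)
  ck_df <- as.data.frame(c_k)
  names(ck_df) <- paste0("c_", seq_len(k))
  out <- cbind(out, ck_df)
  out$order_rel <- ord / max(ord)
  out$c_rel <- if (max(cc) > 0) cc / max(cc) else 0
  out
}

#' @rdname metrics_timeseries
#' @export
metrics_timeseries.gard_trajectory <- function(x, walk, env = NULL,
                                               epsilon = 0.01,
                                               unit_sizes = FALSE, ...) {
  if (is.null(env)) env <- x$env
  rec <- x$records
  ncols <- paste0("n_", seq_len(x$n_types))
  n_gen <- max(rec$t)
  rows_at <- split(seq_len(nrow(rec)), rec$t)
  S_r <- numeric(n_gen)
  cc <- numeric(n_gen)
  cur_env <- env
  for (g in seq_len(n_gen)) {
    for (s in x$env_schedule) if (s$from == g) cur_env$pi <- s$pi
    counts <- as.matrix(rec[rows_at[[as.character(g)]], ncols, drop = FALSE])
    sizes <- rowSums(counts)
    profiles <- counts / sizes
    nk <- if (unit_sizes) rep(1, length(sizes)) else sizes
    pop <- compotype_population(rep(1 / length(sizes), length(sizes)),
                                profiles, nk)
    reps <- apply(profiles, 1, effective_repertoire, epsilon = epsilon)
    S_r[g] <- sequential_entropy(pop, cur_env, walk)
    cc[g] <- complexity(pop, reps, walk)$c
  }
  ord <- order_value(S_r)
  out <- data.frame(t = seq_len(n_gen), S_r = S_r, order = ord, c = cc)
  out$order_rel <- ord / max(ord)
  out$c_rel <- if (max(cc) > 0) cc / max(cc) else 0
  out
}
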