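# The GARD rate law and its stochastic realization for a single assembly.
#
# The net accretion rate of type i in an assembly of composition n with total
# size N is
#
#   dn_i/dt = (k_i pi_i N - k_{-i} n_i) * (1 + (1/N) sum_j beta_ij n_j)
#
# under the default rate_form = "factor_on_net" (mutual catalysis accelerates
# entry and exit alike, so it biases kinetics without shifting the
# equilibrium composition). Under "factor_on_backward" the catalytic factor
# multiplies only the backward term k_{-i} n_i.

rate_forms <- c("factor_on_net", "factor_on_backward")

# Internal: gain/loss propensities for one elementary event.
# Returns list(gain, loss), each length n_types. A single-molecule assembly
# cannot lose its last molecule (it would dissolve), so losses vanish at
# N = 1.
propensities <- function(counts, env, beta, rate_form) {
  N <- sum(counts)
  f <- 1 + as.vector(beta %*% counts) / N
  loss <- if (N <= 1) counts * 0 else env$k_bwd * counts
  if (rate_form == "factor_on_net") {
    list(gain = env$k_fwd * env$pi * N * f, loss = loss * f)
  } else {
    list(gain = env$k_fwd * env$pi * N, loss = loss * f)
  }
}

#' Net accretion rates of the GARD rate law
#'
#' Evaluates, for every amphiphile type, the deterministic net rate
#' \eqn{dn_i/dt} at the assembly's current composition.
#'
#' @param assembly A [assembly()] or a raw counts vector.
#' @param env A [gard_environment()].
#' @param beta Square catalytic matrix (see [beta_matrix()]).
#' @param rate_form `"factor_on_net"` (default): the catalytic factor
#'   `1 + (1/N) sum_j beta_ij n_j` multiplies the whole net term;
#'   `"factor_on_backward"`: it multiplies only the backward term.
#' @return Numeric vector of net rates (molecules/time), one per type.
#' @examples
#' env <- gard_environment(c(0.5, 0.5), k_fwd = 1, k_bwd = 1)
#' net_rates(c(1, 3), env, matrix(0, 2, 2))
#' @export
net_rates <- function(assembly, env, beta,
                      rate_form = c("factor_on_net", "factor_on_backward")) {
  rate_form <- match.arg(rate_form)
  counts <- as_counts(assembly)
  check_dims(counts, env, beta)
  N <- sum(counts)
  if (N < 1) stop("degenerate assembly: size is 0", call. = FALSE)
  f <- 1 + as.vector(beta %*% counts) / N
  net <- env$k_fwd * env$pi * N - env$k_bwd * counts
  if (rate_form == "factor_on_net") net * f
  else env$k_fwd * env$pi * N - env$k_bwd * counts * f
}

#' One elementary stochastic accretion/release event
#'
#' Applies a single kinetic Monte-Carlo event to the assembly: a type-i gain
#' with propensity proportional to the forward term, or a type-i loss with
#' propensity proportional to the backward term, each scaled by the catalytic
#' factor implied by `rate_form`. Uses the current R random stream.
#'
#' @inheritParams net_rates
#' @return A [assembly()] whose size differs by exactly one molecule.
#' @export
grow_step <- function(assembly, env, beta,
                      rate_form = c("factor_on_net", "factor_on_backward")) {
  rate_form <- match.arg(rate_form)
  counts <- as_counts(assembly)
  check_dims(counts, env, beta)
  if (sum(counts) < 1) stop("degenerate assembly: size is 0", call. = FALSE)
  assembly(grow_step_counts(counts, env, beta, rate_form))
}

# Internal fast path: raw counts in, raw counts out, no validation.
grow_step_counts <- function(counts, env, beta, rate_form) {
  pr <- propensities(counts, env, beta, rate_form)
  a <- c(pr$gain, pr$loss)
  tot <- sum(a)
  if (tot <= 0) stop("stalled assembly: all event propensities are zero",
                     call. = FALSE)
  ev <- sample.int(length(a), 1L, prob = a)
  n <- length(counts)
  if (ev <= n) counts[ev] <- counts[ev] + 1
  else counts[ev - n] <- counts[ev - n] - 1
  counts
}

#' Grow an assembly to the splitting size
#'
#' Repeats elementary events until the assembly reaches `split_size`
#' molecules. An iteration cap (default 1e6 events) guards against
#' configurations where losses dominate and the size random-walks without
#' progress.
#'
#' @inheritParams net_rates
#' @param split_size Target total molecule number; must exceed the current
#'   size.
#' @param max_events Iteration cap before a progress error is raised.
#' @return A [assembly()] of exactly `split_size` molecules.
#' @export
grow_to_split <- function(assembly, env, beta, split_size,
                          rate_form = c("factor_on_net", "factor_on_backward"),
                          max_events = 1e6) {
  rate_form <- match.arg(rate_form)
  counts <- as_counts(assembly)
  check_dims(counts, env, beta)
  if (sum(counts) >= split_size) {
    stop("assembly size (", sum(counts), ") must be below split_size (",
         split_size, ")", call. = FALSE)
  }
  assembly(grow_to_split_counts(counts, env, beta, split_size, rate_form,
                                max_events))
}

grow_to_split_counts <- function(counts, env, beta, split_size, rate_form,
                                 max_events = 1e6) {
  kf_pi <- env$k_fwd * env$pi
  k_bwd <- env$k_bwd
  on_net <- rate_form == "factor_on_net"
  n <- length(counts)
  it <- 0L
  N <- sum(counts)
  while (N < split_size) {
    it <- it + 1L
    if (it > max_events) {
      stop("grow_to_split: no progress after ", max_events, " events",
           call. = FALSE)
    }
    f <- 1 + as.vector(beta %*% counts) / N
    if (on_net) {
      gain <- kf_pi * N * f
      loss <- if (N <= 1) counts * 0 else k_bwd * counts * f
    } else {
      gain <- kf_pi * N
      loss <- if (N <= 1) counts * 0 else k_bwd * counts * f
    }
    a <- c(gain, loss)
    tot <- sum(a)
    if (tot <= 0) stop("stalled assembly: all event propensities are zero",
                       call. = FALSE)
    ev <- sample.int(2L * n, 1L, prob = a)
    if (ev <= n) {
      counts[ev] <- counts[ev] + 1
      N <- N + 1
    } else {
      counts[ev - n] <- counts[ev - n] - 1
      N <- N - 1
    }
  }
  counts
}

# Deterministic fixed-step Euler growth of the mean-field rate law.
# Counts become real-valued; integration stops when total size reaches
# split_size (the final step is shortened to land on it exactly).
euler_grow_counts <- function(counts, env, beta, split_size, rate_form,
                              dt = 0.01, max_steps = 1e7) {
  it <- 0
  repeat {
    it <- it + 1
    if (it > max_steps) stop("euler growth: no progress", call. = FALSE)
    N <- sum(counts)
    if (N >= split_size) break
    r <- net_rates(counts, env, beta, rate_form)
    tot <- sum(r)
    if (tot <= 0) stop("euler growth: net growth rate is nonpositive",
                       call. = FALSE)
    step <- dt
    if (N + tot * dt > split_size) step <- (split_size - N) / tot
    counts <- pmax(counts + r * step, 0)
  }
  counts
}

#' Split a grown assembly into two progeny
#'
#' Partitions the molecules into two equal halves by sampling without
#' replacement (a multivariate hypergeometric halving), the unbiased model of
#' fission transmitting compositional information to the next generation.
#' Per-type progeny counts always sum exactly to the parent counts.
#'
#' @param assembly A [assembly()] (or counts vector) of even total size.
#' @return List of two [assembly()] objects of equal size.
#' @examples
#' set.seed(1)
#' split_assembly(c(4, 2))
#' @export
split_assembly <- function(assembly) {
  counts <- as_counts(assembly)
  N <- sum(counts)
  if (N < 2 || N %% 2 != 0) {
    stop("split requires an even assembly size >= 2 (got ", N, ")",
         call. = FALSE)
  }
  first <- rmvhyper_half(counts)
  list(assembly(first), assembly(counts - first))
}

# Draw one multivariate hypergeometric half of an integer counts vector,
# by conditional univariate hypergeometric draws.
rmvhyper_half <- function(counts) {
  N <- sum(counts)
  k <- N / 2
  out <- numeric(length(counts))
  remaining <- N
  for (i in seq_along(counts)) {
    if (k <= 0) break
    remaining <- remaining - counts[i]
    out[i] <- stats::rhyper(1, counts[i], remaining, k)
    k <- k - out[i]
  }
  out
}
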