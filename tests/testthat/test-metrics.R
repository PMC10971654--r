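# Sequential entropy, order, complexity, and the information coding.

R_gas <- gard_constants$R

test_that("delta-distributed systems carry zero sequential entropy", {
  env <- uniform_env(5)
  pop <- compotype_population(1, rbind(c(1, 0, 0, 0, 0)), 20)
  wp <- walk_params(M = 0, N_rw = 100, N = 20)
  expect_equal(as.numeric(sequential_entropy(pop, env, wp)), 0)
})

test_that("the pure-monomer uniform system recovers the ideal-mixing limit", {
  env <- uniform_env(20)
  pop <- compotype_population(1, rbind(rep(1 / 20, 20)), 30)
  wp <- walk_params(M = Inf, N_rw = 12345, N = 30, molar = TRUE)
  s <- sequential_entropy(pop, env, wp)
  expect_equal(as.numeric(s), R_gas * log(20), tolerance = 1e-12)
  expect_equal(R_gas * log(20), 24.9, tolerance = 1e-3)
  expect_equal(order_value(s), 1 / (R_gas * log(20)), tolerance = 1e-12)
})

test_that("order is the reciprocal entropy with a degenerate sentinel", {
  expect_equal(order_value(2), 0.5)
  expect_warning(o <- order_value(0), "perfectly ordered")
  expect_identical(o, Inf)
  s <- sort(runif(10, 0.1, 5))
  expect_true(all(diff(order_value(s)) < 0))
  expect_error(order_value(-1), ">= 0")
})

test_that("the walk sampler agrees with the closed form on a mixed fixture", {
  env <- gard_environment(c(0.2, 0.3, 0.5))
  pop <- compotype_population(
    c(0.4, 0.6), rbind(c(0.7, 0.2, 0.1), c(0.1, 0.1, 0.8)), c(20, 30))
  # N set to the population mean size so segments tile N_rw exactly
  wp <- walk_params(M = 5, N_rw = 20 * (5 + 26), N = 26)
  set.seed(14)
  sw <- sample_walk_string(pop, env, wp, n_strings = 8000)
  closed <- attr(sequential_entropy(pop, env, wp), "w_log")
  expect_lt(abs(sw$entropy - closed), 3 * sw$se)
})

test_that("degenerate sampler inputs give constant strings with zero entropy", {
  env <- gard_environment(c(1, 0))
  pop <- compotype_population(1, rbind(c(1, 0)), 10)
  wp <- walk_params(M = 2, N_rw = 48, N = 10)
  set.seed(1)
  sw <- sample_walk_string(pop, env, wp, n_strings = 50,
                           return_strings = TRUE)
  expect_equal(sw$entropy, 0)
  expect_true(all(vapply(sw$strings, function(s) all(s == 1L), logical(1))))
  expect_equal(length(sw$strings[[1]]), 4 * (2 + 10))
})

test_that("with M = 0 the sampler converges to the micelle term alone", {
  env <- uniform_env(4)
  p <- c(0.5, 0.25, 0.15, 0.1)
  pop <- compotype_population(1, rbind(p), 25)
  wp <- walk_params(M = 0, N_rw = 10 * 25, N = 25)
  set.seed(15)
  sw <- sample_walk_string(pop, env, wp, n_strings = 8000)
  truth <- 10 * 25 * -sum(p * log(p))
  expect_lt(abs(sw$entropy - truth), 3 * sw$se)
})

test_that("variability equals the enumeration oracle on small repertoires", {
  expect_equal(variability(1, 7), 1)
  expect_equal(variability(2, 2), 3)
  expect_equal(variability(3, 4), 15)
  for (k in 1:5) for (n in 0:8) {
    expect_equal(variability(k, n), count_compositions(k, n))
  }
  # log-space path stays finite far beyond double-precision factorials
  expect_true(is.finite(variability(200, 5000, log2 = TRUE)))
  expect_error(variability(0, 3), ">= 1")
})

test_that("the effective repertoire counts materially participating types", {
  expect_equal(effective_repertoire(c(1, rep(0, 19))), 1L)
  expect_equal(effective_repertoire(rep(1 / 20, 20)), 20L)
  expect_equal(effective_repertoire(c(0.5, 0.3, 0.15, 0.05, 0), 0.10), 3L)
  expect_error(effective_repertoire(c(0.004, 0.996), 0.999), "lower epsilon")
})

test_that("complexity is the population-weighted code size with expected structure", {
  wp <- walk_params(M = 0, N_rw = 2, N = 2)   # N_rw / (M + N) = 1
  pop0 <- compotype_population(0, rbind(c(0.5, 0.5)), 2)
  expect_equal(complexity(pop0, 2L, wp)$c, 0)

  pop1 <- compotype_population(1, rbind(c(0.5, 0.5)), 2)
  expect_equal(complexity(pop1, 2L, wp)$c, log2(3), tolerance = 1e-12)

  # linear in P_k and additive over compotypes
  popA <- compotype_population(c(0.2, 0.3),
                               rbind(c(0.5, 0.5), c(0.9, 0.1)), c(4, 6))
  popB <- compotype_population(c(0.4, 0.3),
                               rbind(c(0.5, 0.5), c(0.9, 0.1)), c(4, 6))
  cA <- complexity(popA, c(2L, 2L), wp)
  cB <- complexity(popB, c(2L, 2L), wp)
  expect_equal(cB$c_k[1], 2 * cA$c_k[1], tolerance = 1e-12)
  expect_equal(cA$c, sum(cA$c_k))

  # nondecreasing in repertoire and in size
  base <- complexity(pop1, 2L, wp)$c
  expect_gte(complexity(pop1, 3L, wp)$c, base)
  pop_big <- compotype_population(1, rbind(c(0.5, 0.5)), 5)
  expect_gte(complexity(pop_big, 2L, wp)$c, base)
})

test_that("molar conversion rescales entropy and complexity by N_A / N_rw", {
  env <- gard_environment(c(0.3, 0.7))
  pop <- compotype_population(0.8, rbind(c(0.6, 0.4)), 15)
  per <- walk_params(M = 4, N_rw = 1e5, N = 15)
  mol <- walk_params(M = 4, N_rw = 1e5, N = 15, molar = TRUE)
  s_per <- as.numeric(sequential_entropy(pop, env, per))
  s_mol <- as.numeric(sequential_entropy(pop, env, mol))
  expect_equal(s_mol / s_per, gard_constants$N_A / 1e5, tolerance = 1e-12)
  c_per <- complexity(pop, 2L, per)$c
  c_mol <- complexity(pop, 2L, mol)$c
  expect_equal(c_mol / c_per, gard_constants$N_A / 1e5, tolerance = 1e-12)
})

test_that("replacing any profile by the uniform one never decreases entropy", {
  set.seed(16)
  env <- uniform_env(6)
  wp <- walk_params(M = 3, N_rw = 500, N = 20)
  for (i in 1:50) {
    K <- sample(1:3, 1)
    P <- runif(K); P <- P / sum(P)
    prof <- matrix(rgamma(K * 6, 0.6), K)
    prof <- prof / rowSums(prof)
    sizes <- runif(K, 5, 40)
    pop <- compotype_population(P, prof, sizes)
    s0 <- as.numeric(sequential_entropy(pop, env, wp))
    j <- sample(K, 1)
    prof2 <- prof; prof2[j, ] <- 1 / 6
    s1 <- as.numeric(sequential_entropy(
      compotype_population(P, prof2, sizes), env, wp))
    expect_gte(s1, s0 - 1e-12 * max(1, s0))
  }
})

test_that("the binary coding yields one bit per amphiphile type", {
  out <- binary_information(c(0.4, 0.1, 0.5), rep(1 / 3, 3))
  expect_equal(out$codeword, c(1L, 0L, 1L))
  expect_equal(out$bits, 3)
  same <- binary_information(rep(0.25, 4), rep(0.25, 4))
  expect_equal(same$codeword, rep(1L, 4))  # unchanged counts as enriched
  expect_equal(same$bits, 4)
  expect_error(binary_information(c(0.5, 0.5), c(1)), "equal length")
})

test_that("RNA-equivalent length is the two-bit-per-base ceiling", {
  expect_equal(rna_equivalent_length(20), 10)
  expect_equal(rna_equivalent_length(0), 0)
  expect_equal(rna_equivalent_length(21), 11)
})

test_that("frozen compotype series give constant metrics over time", {
  s <- fixture_compotype_series("fig4_like", n_generations = 50)
  s$P <- matrix(rep(c(0.3, 0.3, 0.2), each = 50), 50)
  colnames(s$P) <- paste0("P_", 1:3)
  s$drift <- 1 - rowSums(s$P)
  wp <- walk_params(M = 10, N_rw = 1e4, N = 30)
  m <- metrics_timeseries(s, wp)
  expect_equal(diff(range(m$S_r)), 0)
  expect_equal(diff(range(m$c)), 0)
})

test_that("a ramping narrow compotype raises order and complexity together", {
  n <- 60
  env <- uniform_env(20)
  narrow <- c(rep(0.25, 4), rep(0, 16))
  s <- structure(
    list(t = seq_len(n),
         P = matrix(seq(0, 0.8, length.out = n), n, 1,
                    dimnames = list(NULL, "P_1")),
         drift = 1 - seq(0, 0.8, length.out = n),
         profiles = rbind(narrow), N_k = 30, assignments = NULL,
         eta = 0.9, k = 1L, weighting = "assemblies", env = env,
         env_schedule = NULL),
    class = "gard_compotype_series")
  m <- metrics_timeseries(s, walk_params(M = 10, N_rw = 1e4, N = 30))
  expect_true(all(diff(m$order) > 0))
  expect_true(all(diff(m$c) > 0))
})

test_that("replacing a narrow compotype by a broader one costs order while complexity rises", {
  n <- 60
  env <- uniform_env(20)
  narrow <- c(0.5, 0.5, rep(0, 18))
  broad <- c(rep(1 / 6, 6), rep(0, 14))
  P_narrow <- seq(0.6, 0.2, length.out = n)
  P_broad <- seq(0.2, 0.7, length.out = n)
  s <- structure(
    list(t = seq_len(n), P = cbind(P_1 = P_narrow, P_2 = P_broad),
         drift = 1 - P_narrow - P_broad,
         profiles = rbind(narrow, broad), N_k = c(30, 30),
         assignments = NULL, eta = 0.9, k = 2L, weighting = "assemblies",
         env = env, env_schedule = NULL),
    class = "gard_compotype_series")
  m <- metrics_timeseries(s, walk_params(M = 2, N_rw = 1e4, N = 30))
  expect_true(all(diff(m$order) < 0))
  expect_true(all(diff(m$c) > 0))
})

test_that("per-micelle metrics run on a trajectory and differ from the compotype view", {
  env <- uniform_env(4)
  tr <- run_reactor(env, zero_beta(4), reactor_config(5, 20, 60, seed = 6))
  wp <- walk_params(M = 5, N_rw = 1e4, N = 10)
  m_mic <- metrics_timeseries(tr, wp)
  expect_equal(nrow(m_mic), 60)
  expect_true(all(m_mic$S_r > 0))
  m_unit <- metrics_timeseries(tr, wp, unit_sizes = TRUE)
  expect_true(all(m_unit$S_r < m_mic$S_r))
  s <- cluster_compotypes(tr, k = 1, eta = 0.8)
  m_cmp <- metrics_timeseries(s, wp)
  rel_diff <- mean(abs(m_cmp$S_r - m_mic$S_r)) / mean(m_mic$S_r)
  expect_gt(rel_diff, 1e-6)
})
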