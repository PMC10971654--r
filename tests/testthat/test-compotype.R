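# Composome detection and compotype clustering.

test_that("compositional similarity matches hand arithmetic", {
  expect_equal(similarity(c(3, 1, 0), c(3, 1, 0)), 1)
  expect_equal(similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(similarity(c(0, 0), c(1, 0)), "zero vector")
  expect_error(similarity(c(1, 0, 0), c(1, 0)), "equal length")
})

test_that("similarity is symmetric and scale-invariant", {
  set.seed(8)
  for (i in 1:25) {
    a <- runif(5); b <- runif(5)
    expect_equal(similarity(a, b), similarity(b, a))
    expect_equal(similarity(a, b), similarity(3.7 * a, 0.2 * b),
                 tolerance = 1e-12)
  }
})

test_that("the composome test thresholds parent-progeny similarity", {
  expect_true(is_composome(c(4, 2), c(2, 1), eta = 1 - 1e-12))
  expect_false(is_composome(c(10, 0), c(0, 5), eta = 0.9))
  # similarity((6,2),(2,2)) = 16 / (sqrt(40) sqrt(8)) ~ 0.894 < 0.9
  expect_equal(similarity(c(6, 2), c(2, 2)), 16 / (sqrt(40) * sqrt(8)))
  expect_false(is_composome(c(6, 2), c(2, 2), eta = 0.9))
  expect_true(is_composome(c(6, 2), c(2, 2), eta = 0.89))
})

two_family_trajectory <- function(n_gen, cA, cB) {
  n <- length(cA)
  ids <- c(1L, 2L, 3L, 4L)
  parents <- rep(NA_integer_, 4)
  comp <- rbind(cA, cA, cB, cB)
  next_id <- 5L
  rows <- vector("list", n_gen * 4)
  r <- 0L
  for (g in seq_len(n_gen)) {
    slots <- if (g %% 2 == 1) 1:2 else 3:4
    pid <- ids[slots[1]]
    ids[slots] <- c(next_id, next_id + 1L)
    parents[slots] <- pid
    next_id <- next_id + 2L
    for (a in 1:4) {
      r <- r + 1L
      rows[[r]] <- data.frame(t = g, assembly_id = ids[a],
                              parent_id = parents[a],
                              as.data.frame(t(comp[a, ])))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[4:(3 + n)] <- paste0("n_", seq_len(n))
  fake_trajectory(out, uniform_env(n))
}

test_that("a perfectly reproducing population is one compotype with P = 1", {
  counts <- c(12, 6, 2)
  tr <- fake_trajectory(perfect_records(counts, 30), uniform_env(3))
  s <- cluster_compotypes(tr, k = 1, eta = 0.99)
  expect_equal(unname(s$P[5:30, 1]), rep(1, 26))
  expect_equal(as.numeric(s$profiles[1, ]), counts / sum(counts),
               tolerance = 1e-9)
  expect_equal(s$drift[5:30], rep(0, 26))
})

test_that("planted composition clouds are recovered by the clustering", {
  cA <- c(30, 10, 0, 0)
  cB <- c(0, 0, 24, 16)
  tr <- two_family_trajectory(40, cA, cB)
  s <- cluster_compotypes(tr, k = 2, eta = 0.95)
  got <- s$profiles[order(s$profiles[, 1]), ]
  expect_equal(as.numeric(got[2, ]), cA / sum(cA), tolerance = 1e-9)
  expect_equal(as.numeric(got[1, ]), cB / sum(cB), tolerance = 1e-9)
  expect_equal(unname(s$P[10, ]), c(0.5, 0.5))
  # at every generation the fractions and drift close the balance exactly
  expect_equal(rowSums(s$P) + s$drift, rep(1, 40))
})

test_that("labels are stable across reruns with the same seed", {
  tr <- two_family_trajectory(30, c(20, 20, 0, 0), c(0, 5, 15, 20))
  s1 <- cluster_compotypes(tr, k = 2, eta = 0.9, seed = 7)
  s2 <- cluster_compotypes(tr, k = 2, eta = 0.9, seed = 7)
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$P, s2$P)
})

test_that("a non-reproducing population is mostly drift at a strict threshold", {
  env <- uniform_env(6, k_bwd = 1)
  tr <- run_reactor(env, zero_beta(6), reactor_config(8, 20, 400, seed = 3))
  births <- gardsim:::trajectory_births(tr)
  frac_faithful <- mean(births$parent_similarity >= 0.99, na.rm = TRUE)
  expect_lt(frac_faithful, 0.1)
  s <- try(cluster_compotypes(tr, k = 1, eta = 0.99), silent = TRUE)
  if (inherits(s, "gard_compotype_series")) {
    expect_gt(mean(s$drift), 0.85)
    expect_lt(mean(s$P[, 1]), 0.15)
  } else {
    expect_match(attr(s, "condition")$message, "lower k or eta")
  }
})

test_that("the molecule-weighted fractions also close the balance", {
  tr <- two_family_trajectory(20, c(30, 10, 0, 0), c(0, 0, 6, 4))
  s <- cluster_compotypes(tr, k = 2, eta = 0.95, weighting = "molecules")
  expect_equal(rowSums(s$P) + s$drift, rep(1, 20))
  # family A assemblies are 4x heavier, so its molecule share is 0.8
  expect_equal(max(s$P[10, ]), 0.8, tolerance = 1e-9)
})

test_that("clustering errors advise on k and eta", {
  tr <- fake_trajectory(perfect_records(c(5, 5), 10), uniform_env(2))
  expect_error(cluster_compotypes(tr, k = 4, eta = 0.9), "lower k or eta")
})

test_that("takeover detection finds crossings and ignores constant series", {
  mk_series <- function(P, n_types = 4) {
    structure(
      list(t = seq_len(nrow(P)), P = P, drift = 1 - rowSums(P),
           profiles = diag(n_types)[seq_len(ncol(P)), , drop = FALSE],
           N_k = rep(20, ncol(P)), assignments = NULL, eta = 0.9,
           k = ncol(P), weighting = "assemblies", env = uniform_env(n_types),
           env_schedule = NULL),
      class = "gard_compotype_series")
  }
  Tn <- 400
  flat <- mk_series(cbind(rep(0.4, Tn), rep(0.3, Tn)))
  expect_equal(nrow(takeover_summary(flat, window = 21)), 0)

  t <- seq_len(Tn)
  lin <- mk_series(cbind(P_1 = t / Tn * 0.8, P_2 = rep(0.05, Tn),
                         P_3 = (1 - t / Tn) * 0.8))
  ev <- takeover_summary(lin, window = 21)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$k_declining, 3)
  expect_equal(ev$k_rising, 1)
  expect_lt(abs(ev$crossing - Tn / 2), 0.05 * Tn)

  # early red dominance, green overtakes midway
  sig <- function(x) 1 / (1 + exp(-x))
  red <- 0.6 * (1 - sig((t - 200) / 30))
  green <- 0.6 * sig((t - 200) / 30)
  fig6ish <- mk_series(cbind(P_1 = rep(0.1, Tn), P_2 = green, P_3 = red))
  ev2 <- takeover_summary(fig6ish, window = 21)
  expect_true(any(ev2$k_declining == 3 & ev2$k_rising == 2))
})
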