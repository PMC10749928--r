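test_that("power-law conditional sampler reduces to inverse-CDF at M = 0", {
  # M = 0 forces c = 0 for every previous gap
  for (tp in c(1, 2.5, 40)) {
    expect_equal(next_iet_power_law(tp, 2.5, 0, 0.5), 0.5^(-1 / 1.5))
  }
  # analytic-limit branch is continuous with the generic branch
  expect_equal(next_iet_power_law(2, 2.5, 1e-6, 0.3),
               next_iet_power_law(2, 2.5, 0, 0.3), tolerance = 1e-4)
  # large exponent collapses the marginal to its lower bound 1
  expect_equal(next_iet_power_law(1.5, 50, 0, 0.9), 1, tolerance = 0.01)
  expect_true(next_iet_power_law(3, 2.2, 0.3, 0.99) >= 1)
  expect_error(next_iet_power_law(0.5, 2.5, 0, 0.5), "tau_prev")
  expect_error(next_iet_power_law(2, 1.5, 0, 0.5), "alpha")
})

test_that("exponential conditional sampler has the right limits", {
  expect_equal(next_iet_exponential(1, 5, 0, exp(-1)), 5)
  expect_equal(next_iet_exponential(3, 2, 1e-7, 0.4),
               next_iet_exponential(3, 2, 0, 0.4), tolerance = 1e-5)
  expect_error(next_iet_exponential(1, 2, 0.1, 0), "infinite")
  # for a huge previous gap c tends to 4M: check against the explicit formula
  c_lim <- 4 * 0.2
  u <- 0.37
  expected <- 2 * log(2 * c_lim / (c_lim + 1 - sqrt((c_lim + 1)^2 - 4 * c_lim * u)))
  expect_equal(next_iet_exponential(1e9, 2, 0.2, u), expected, tolerance = 1e-8)
})

test_that("copula sequences respect their spec and are seed-deterministic", {
  spec <- copula_spec("power_law", n_events = 50L, alpha = 2.4,
                      memory_target = 0.1, seed = 21L)
  s1 <- generate_copula_sequence(spec)
  s2 <- generate_copula_sequence(spec)
  expect_identical(s1$timestamps, s2$timestamps)
  expect_length(s1$timestamps, 50L)
  expect_length(compute_iets(s1), 49L)
  expect_true(all(compute_iets(s1) >= 1))  # power-law lower bound
  expect_true(all(diff(s1$timestamps) > 0))
  se <- generate_copula_sequence(copula_spec("exponential", n_events = 10L,
                                             mu = 7, memory_target = 0,
                                             seed = 3L))
  expect_equal(se$timestamps[1], 7)  # initial gap equals mu
  expect_error(copula_spec("power_law", n_events = 10, alpha = 3),
               "alpha")
  expect_error(copula_spec("exponential", n_events = 10, mu = -1), "mu")
})

test_that("copula sampling preserves the marginal at moderate memory", {
  # chained draws are lag-1 dependent; test the marginal on a thinned
  # subsample so the KS test's independence assumption holds
  spec <- copula_spec("exponential", n_events = 20000L, mu = 3,
                      memory_target = 0.2, seed = 9L)
  iets <- compute_iets(generate_copula_sequence(spec))
  sub <- iets[seq(5, length(iets), by = 5)]
  ks <- suppressWarnings(stats::ks.test(sub, stats::pexp, rate = 1 / 3))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensemble recipes draw parameters in the documented ranges", {
  ds <- generate_powerlaw_dataset(30L, seed = 5L)
  ns <- vapply(ds, length, integer(1))
  expect_true(all(ns >= 50L & ns <= 500L))
  alphas <- vapply(ds, function(s) s$metadata$alpha, numeric(1))
  expect_true(all(alphas >= 2.1 & alphas <= 2.9))
  Ms <- vapply(ds, function(s) s$metadata$memory_target, numeric(1))
  expect_true(all(abs(Ms) <= 1 / 3))
  first_gaps <- vapply(ds, function(s) s$timestamps[1], numeric(1))
  expect_true(all(first_gaps >= 1 & first_gaps <= 2))
  ds2 <- generate_powerlaw_dataset(30L, seed = 5L)
  expect_identical(lapply(ds, `[[`, "timestamps"),
                   lapply(ds2, `[[`, "timestamps"))
  de <- generate_exponential_dataset(20L, seed = 6L)
  mus <- vapply(de, function(s) s$metadata$mu, numeric(1))
  expect_true(all(mus >= 1 & mus <= 100))
  expect_equal(vapply(de, function(s) s$timestamps[1], numeric(1)), mus)
})

test_that("self-correcting inversion matches numerical root finding", {
  zeta <- 1.3; eta <- 0.4
  set.seed(44)
  n <- 15L
  es <- rexp(n)
  # closed-form path
  t_closed <- numeric(n); t_cur <- 0
  for (i in seq_len(n)) {
    t_cur <- t_cur + log1p(zeta * es[i] * exp((i - 1) * eta - zeta * t_cur)) / zeta
    t_closed[i] <- t_cur
  }
  # independent path: solve the compensator equation numerically
  t_num <- numeric(n); t_cur <- 0
  for (i in seq_len(n)) {
    f <- function(t) {
      stats::integrate(function(s) exp(zeta * s - (i - 1) * eta),
                       t_cur, t, rel.tol = 1e-12)$value - es[i]
    }
    t_cur <- stats::uniroot(f, c(t_cur, t_cur + 100), tol = 1e-12)$root
    t_num[i] <- t_cur
  }
  expect_equal(t_closed, t_num, tolerance = 1e-7)
})

test_that("self-correcting sequences are near-regular with rate zeta/eta", {
  s <- simulate_self_correcting(zeta = 5, eta = 1, n_events = 4000L, seed = 2L)
  iets <- compute_iets(s)
  expect_equal(mean(iets), 1 / 5, tolerance = 0.05)  # rate balance
  expect_lt(burstiness_corrected(iets = iets), 0)    # more regular than Poisson
  s2 <- simulate_self_correcting(n_events = 2000L, seed = 3L)  # defaults
  expect_equal(mean(compute_iets(s2)), 0.2, tolerance = 0.05)
})

test_that("Hawkes simulator has Poisson and clustering limits", {
  s0 <- simulate_hawkes(zeta = 2, eta = 0, horizon = 2000, seed = 8L)
  n0 <- length(s0$timestamps)
  expect_lt(abs(n0 - 4000) / sqrt(4000), 4)  # Poisson count fluctuation
  s1 <- simulate_hawkes(zeta = 1, eta = 0.5, horizon = 1000, seed = 9L)
  # branching-ratio expectation zeta*T/(1 - eta) = 2000; overdispersed count
  expect_lt(abs(length(s1$timestamps) - 2000), 400)
  s2 <- simulate_hawkes(zeta = 1, eta = 0.8, horizon = 500, seed = 10L)
  expect_gt(burstiness_corrected(iets = compute_iets(s2)), 0)  # clustering
  expect_warning(simulate_hawkes(zeta = 1, eta = 1.1, horizon = 5, seed = 1L,
                                 max_events = 200L), "nonstationary")
})
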