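test_that("inter-event times are consecutive differences and validate input", {
  expect_equal(compute_iets(event_sequence(c(0, 1, 3))), c(1, 2))
  expect_equal(compute_iets(c(5, 5.5)), 0.5)
  expect_error(event_sequence(c(1, 1)), "strictly increasing")
  expect_error(compute_iets(c(2, 1)), "strictly increasing")
  expect_error(event_sequence(c(1, 2), observation_end = 1.5), "observation_end")
})

test_that("burstiness matches its defining limits and hand values", {
  expect_equal(burstiness(c(2, 2, 2)), -1)          # regular
  expect_equal(burstiness(c(0, 2)), 0)              # sigma equals mean
  expect_equal(burstiness(c(1, 3)), -1 / 3)         # mean 2, population sd 1
  expect_error(burstiness(c(0, 0, 0)), "undefined")
  expect_error(burstiness(2), "at least 2")
})

test_that("finite-size-corrected burstiness follows the correction formula", {
  expect_equal(burstiness_corrected(r = 0, n = 5), -1)
  expect_equal(burstiness_corrected(r = 0, n = 1000), -1)
  expect_equal(burstiness_corrected(r = 1, n = 5), 0.1835034, tolerance = 1e-6)
  # asymptotic identity with the uncorrected definition (O(1/sqrt(n)))
  for (r in c(0.1, 0.5, 1, 2)) {
    expect_equal(burstiness_corrected(r = r, n = 1e8), (r - 1) / (r + 1),
                 tolerance = 1e-3)
    gap6 <- abs(burstiness_corrected(r = r, n = 1e6) - (r - 1) / (r + 1))
    gap8 <- abs(burstiness_corrected(r = r, n = 1e8) - (r - 1) / (r + 1))
    expect_lt(gap8, gap6 / 5)  # shrinks at the 1/sqrt(n) rate (~10x per 100x n)
  }
  # iets interface is consistent with the (r, n) interface
  iets <- c(1, 4, 2, 8, 3)
  expect_identical(
    burstiness_corrected(iets = iets),
    burstiness_corrected(r = iet_cv(iets), n = length(iets) + 1L)
  )
})

test_that("memory coefficient is the lag-1 Pearson correlation", {
  expect_equal(memory_coefficient(c(1, 2, 1, 2, 1)), -1)
  expect_equal(memory_coefficient(c(1, 2, 3, 4)), 1)
  expect_error(memory_coefficient(c(3, 3, 3, 3)), "zero variance")
  expect_equal(memory_coefficient(c(3, 3, 3, 3), on_degenerate = "zero"), 0)
  # brute-force Pearson with independent summation order
  set.seed(31)
  for (k in c(5L, 17L, 60L)) {
    x <- rexp(k)
    xs <- x[-k]; ys <- x[-1]
    num <- 0
    for (i in seq_len(k - 1L)) {
      num <- num + (xs[i] - mean(xs)) * (ys[i] - mean(ys))
    }
    brute <- num / ((k - 1) * sqrt(mean((xs - mean(xs))^2)) *
                      sqrt(mean((ys - mean(ys))^2)))
    expect_equal(memory_coefficient(x), brute, tolerance = 1e-12)
  }
})

test_that("heterogeneity statistics stay in [-1, 1] on random inputs", {
  set.seed(77)
  for (rep in 1:50) {
    iets <- switch(1L + rep %% 3L,
                   rexp(sample(5:80, 1)),
                   runif(sample(5:80, 1))^(-1 / runif(1, 1, 2)),
                   abs(rnorm(sample(5:80, 1))) + 1e-6)
    B <- burstiness(iets)
    Bn <- burstiness_corrected(iets = iets)
    M <- memory_coefficient(iets, on_degenerate = "zero")
    expect_true(B >= -1 && B <= 1)
    expect_true(Bn >= -1 && Bn <= 1)
    expect_true(M >= -1 && M <= 1)
  }
})

test_that("prefix series is causal, masked early, and matches truncation", {
  seq <- tiny_sequence(n = 25L, seed = 9L)
  bm <- prefix_bm_series(seq)
  expect_equal(nrow(bm), 25L)
  expect_false(any(bm$valid[1:3]))
  expect_true(all(is.na(bm$B[1:3])))
  # final entry equals the whole-sequence statistics
  iets <- compute_iets(seq)
  expect_equal(bm$B[25], burstiness_corrected(iets = iets))
  expect_equal(bm$M[25], memory_coefficient(iets))
  # entry i is bit-identical to computing on the truncated sequence
  for (i in c(5L, 11L, 20L)) {
    trunc <- event_sequence(seq$timestamps[seq_len(i)])
    bt <- prefix_bm_series(trunc)
    expect_identical(bm$B[i], bt$B[i])
    expect_identical(bm$M[i], bt$M[i])
  }
  # causality: perturbing later events leaves earlier entries untouched
  pert <- seq$timestamps
  pert[21:25] <- pert[21:25] + cumsum(runif(5, 0.5, 2))
  bp <- prefix_bm_series(event_sequence(pert))
  expect_identical(bm$B[1:20], bp$B[1:20])
  expect_identical(bm$M[1:20], bp$M[1:20])
})

test_that("log-binned histogram is a normalized density with correct tail slope", {
  h1 <- log_binned_iet_histogram(rep(3.7, 100))
  expect_equal(sum(h1$count > 0), 1L)  # all mass in one bin
  expect_equal(sum(h1$density * (h1$bin_hi - h1$bin_lo)), 1, tolerance = 1e-12)
  # inverse-CDF oracle: P(tau) ~ tau^(-2.4) on tau >= 1
  set.seed(12)
  tau <- runif(1e5)^(-1 / 1.4)
  h <- log_binned_iet_histogram(tau, bins_per_decade = 8)
  keep <- h$density > 0 & h$count >= 10
  fit <- lm(log(density) ~ log(bin_center), data = h[keep, ])
  expect_equal(unname(coef(fit)[2]), -2.4, tolerance = 0.1)
  expect_error(log_binned_iet_histogram(c(1, -2)), "positive")
})

test_that("dataset summary uses the per-sequence ensemble convention", {
  ds <- fixture_suite(seed = 3L, n_sequences = 5L)$powerlaw
  s <- dataset_summary(ds)
  expect_equal(nrow(s$per_sequence), 5L)
  manual_B <- mean(vapply(ds, function(x) {
    burstiness_corrected(iets = compute_iets(x))
  }, numeric(1)))
  expect_equal(s$ensemble["mean", "B"], manual_B)
  # single-sequence ensemble has zero spread
  s1 <- dataset_summary(ds[1])
  expect_equal(unname(unlist(s1$ensemble["sd", ])), c(0, 0, 0))
})
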