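test_that("time loss is the sum of squared prediction errors", {
  expect_equal(loss_time(c(2, 3), c(2, 3)), 0)
  expect_equal(loss_time(c(2, 3), c(2, 4)), 1)
  expect_gte(loss_time(rnorm(5), rnorm(5)), 0)
  expect_error(loss_time(1:3, 1:2), "align")
})

test_that("log-likelihood has the closed-form constant-intensity value", {
  # unit intensity, events tiling [0, T]: LL = -T
  tt <- c(0.7, 1.9, 3.2, 4.0)
  expect_equal(
    loss_loglikelihood(rep(1, 4), rep(1, 4), diff(c(0, tt))),
    -4.0
  )
  expect_error(loss_loglikelihood(c(1, -1), 1, 1), "positive")
})

test_that("closed-form non-event integral agrees with adaptive quadrature", {
  set.seed(15)
  for (rep in 1:5) {
    seq <- tiny_sequence(n = 10L, seed = rep)
    cfg <- tiny_config()
    sd <- prepare_sequence(seq, cfg)
    params <- bmt_init_params(cfg, seed = rep)
    fwd <- bmt_forward(params, cfg, sd)
    closed <- sum(fwd$lambda * sd$iets)
    lam_fun <- stats::stepfun(sd$times[-sd$n], c(fwd$lambda[1], fwd$lambda))
    quad <- sum(vapply(seq_len(sd$n - 1L), function(i) {
      stats::integrate(function(s) lam_fun(s), sd$times[i], sd$times[i + 1L],
                       rel.tol = 1e-10)$value
    }, numeric(1)))
    expect_equal(closed, quad, tolerance = 1e-6)
  }
})

test_that("token cross-entropy matches closed forms and clamps zero mass", {
  p <- diag(4)  # perfect one-hot predictions
  expect_equal(loss_bm_crossentropy(0:3, p), 0, tolerance = 1e-10)
  u <- matrix(1 / 1600, nrow = 3, ncol = 1600)
  expect_equal(loss_bm_crossentropy(c(5L, 90L, 1599L), u), 3 * log(1600))
  z <- matrix(c(0, 1), nrow = 1)
  expect_true(is.finite(loss_bm_crossentropy(0L, z)))
  expect_equal(loss_bm_crossentropy(0L, z), -log(1e-12))
})

test_that("value losses are squared sums, symmetric in error sign", {
  out <- loss_bm_values(rep(0.5, 7), rep(0.4, 7), rep(0, 7), rep(0.1, 7))
  expect_equal(unname(out["L_B"]), 0.01 * 7, tolerance = 1e-12)
  expect_equal(unname(out["L_M"]), 0.01 * 7, tolerance = 1e-12)
  flip <- loss_bm_values(rep(0.5, 7), rep(0.6, 7), rep(0, 7), rep(-0.1, 7))
  expect_equal(out, flip)
})

test_that("total loss weighting respects variant constraints", {
  comp <- list(L_t = 2, LL = -3, L_BM = 5, L_B = 7, L_M = 11)
  w0 <- loss_weights(0, 0, 0, 0)
  expect_equal(loss_bundle(comp, w0, "BMT")$total, 2)
  wd <- loss_weights()
  expect_equal(unclass(wd), c(alpha1 = 1e3, alpha2 = 4e3, alpha3 = 1e4,
                              alpha4 = 1e4))
  b <- loss_bundle(comp, wd, "BMT")
  expect_equal(b$total, 2 + 1e3 * 3 + 4e3 * 5 + 1e4 * 7 + 1e4 * 11)
  expect_equal(b$L_lambda, 3)
  # linearity in a component
  b2 <- loss_bundle(utils::modifyList(comp, list(L_B = 14)), wd, "BMT")
  expect_equal(b2$total - b$total, 1e4 * 7)
  expect_error(loss_bundle(comp, wd, "NoE&NoL"), "requires zero")
  expect_error(loss_weights(-1), "non-negative")
  expect_equal(unclass(variant_weights("NoE&L"))[c("alpha2", "alpha3")],
               c(alpha2 = 0, alpha3 = 1e4))
  expect_equal(sum(unclass(variant_weights("E&NoL"))[-1]), 0)
})

test_that("masked prefix positions contribute exactly zero loss", {
  seq <- tiny_sequence(n = 12L)
  cfg <- tiny_config()
  sd <- prepare_sequence(seq, cfg)
  params <- bmt_init_params(cfg, seed = 3L)
  f1 <- bmt_forward(params, cfg, sd)
  # corrupt the masked entries: losses must not change
  sd2 <- sd
  inv <- !sd2$valid
  sd2$B[inv] <- 99
  sd2$M[inv] <- -99
  f2 <- bmt_forward(params, cfg, sd2)
  expect_identical(f1$loss$L_B, f2$loss$L_B)
  expect_identical(f1$loss$L_M, f2$loss$L_M)
  expect_identical(f1$loss$L_BM, f2$loss$L_BM)
})

test_that("analytic gradients match finite differences on tiny models", {
  seq <- tiny_sequence(n = 11L, seed = 17L)
  for (variant in c("BMT", "NoE&L")) {
    cfg <- tiny_config(variant)
    sd <- prepare_sequence(seq, cfg)
    params <- bmt_init_params(cfg, seed = 8L)
    w <- variant_weights(variant, loss_weights(2, 3, 4, 5))
    ga <- analytic_grad_flat(params, cfg, sd, w)
    set.seed(100)
    coords <- sample(length(ga), 40L)
    gn <- numeric_grad(params, cfg, sd, w, coords)
    rel <- abs(ga[coords] - gn) / pmax(abs(gn) + abs(ga[coords]), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})
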