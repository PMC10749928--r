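test_that("dataset splitting is a seeded partition", {
  idx <- split_dataset(100L, seed = 4L)
  expect_length(idx$train, 70L)
  expect_length(idx$val, 10L)
  expect_length(idx$test, 20L)
  expect_setequal(c(idx$train, idx$val, idx$test), 1:100)
  expect_identical(idx, split_dataset(100L, seed = 4L))
  expect_error(split_dataset(10L, fractions = c(0.5, 0.5, 0.5)), "summing")
})

test_that("training reduces the loss and is seed-deterministic", {
  ds <- fixture_suite(seed = 11L, n_sequences = 12L,
                      n_range = c(20L, 40L))$powerlaw
  cfg <- tiny_config(dropout = 0.1)
  m1 <- train_bmt(ds, cfg, epochs = 5L, lr = 3e-3, batch_size = 4L,
                  seed = 2L, patience = Inf)
  expect_lt(tail(m1$history$train_total, 1), m1$history$train_total[1])
  m2 <- train_bmt(ds, cfg, epochs = 5L, lr = 3e-3, batch_size = 4L,
                  seed = 2L, patience = Inf)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("the control variant trains with the B&M machinery disabled", {
  ds <- fixture_suite(seed = 12L, n_sequences = 10L,
                      n_range = c(20L, 35L))$powerlaw
  cfg <- tiny_config("NoE&NoL")
  mdl <- train_bmt(ds, cfg, epochs = 2L, lr = 1e-3, batch_size = 4L, seed = 1L)
  expect_null(mdl$params$W_E)
  expect_null(mdl$params$W_BM)
  expect_equal(sum(unclass(mdl$weights)[c("alpha2", "alpha3", "alpha4")]), 0)
  ev <- evaluate_bmt(mdl, ds[mdl$split$test])
  expect_true(is.na(ev$ce_bm_per_event))
  expect_gte(ev$rmse_time, 0)
})

test_that("evaluation pools squared errors over all predicted events", {
  ds <- fixture_suite(seed = 13L, n_sequences = 6L,
                      n_range = c(15L, 25L))$exponential
  cfg <- tiny_config()
  mdl <- train_bmt(ds, cfg, epochs = 1L, lr = 1e-3, batch_size = 4L, seed = 3L)
  ev <- evaluate_bmt(mdl, ds)
  # independent recomputation of the pooled RMSE from forward passes
  sse <- 0; k <- 0
  for (s in ds) {
    sd <- prepare_sequence(s, cfg)
    fwd <- bmt_forward(mdl$params, cfg, sd)
    sse <- sse + sum((sd$times[-1] - fwd$that[seq_len(sd$n - 1L)])^2)
    k <- k + sd$n - 1L
  }
  expect_equal(ev$rmse_time, sqrt(sse / k), tolerance = 1e-12)
  expect_equal(ev$n_events, k)
  expect_error(evaluate_bmt(mdl, event_dataset(list())), "empty")
})

test_that("checkpoints round-trip parameters and configuration", {
  ds <- fixture_suite(seed = 14L, n_sequences = 8L,
                      n_range = c(15L, 25L))$powerlaw
  cfg <- tiny_config()
  mdl <- train_bmt(ds, cfg, epochs = 1L, lr = 1e-3, batch_size = 4L, seed = 5L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(mdl, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, mdl$params)
  expect_identical(unclass(back$cfg), unclass(mdl$cfg))
  e1 <- evaluate_bmt(mdl, ds[mdl$split$test])
  e2 <- evaluate_bmt(back, ds[mdl$split$test])
  expect_identical(e1$rmse_time, e2$rmse_time)
  unlink(c(path, paste0(path, ".yaml")))
})

test_that("the ablation harness emits the six-variant report shape", {
  ds <- fixture_suite(seed = 15L, n_sequences = 12L,
                      n_range = c(15L, 30L))$powerlaw
  res <- run_ablation_suite(
    ds, seeds = 1L,
    cfg_fn = function(variant) tiny_config(variant, dropout = 0.1),
    epochs = 1L, lr = 1e-3, batch_size = 4L
  )
  expect_equal(nrow(res$table), 6L)
  expect_setequal(res$table$variant,
                  c("NoE&NoL", "NoE&L", "E&NoL", "B", "M", "BMT"))
  # cross-entropy reported only for variants with the joint token head
  expect_identical(res$table$ce_bm[res$table$variant == "NoE&NoL"], "N/A")
  expect_identical(res$table$ce_bm[res$table$variant == "B"], "N/A")
  expect_false(any(res$table$ce_bm[res$table$variant %in%
                                     c("BMT", "E&NoL")] == "N/A"))
  expect_true(all(is.finite(res$runs$rmse_time)))
  # identical seed and variant reproduce the identical report
  res2 <- run_ablation_suite(
    ds, variants = "BMT", seeds = 1L,
    cfg_fn = function(variant) tiny_config(variant, dropout = 0.1),
    epochs = 1L, lr = 1e-3, batch_size = 4L
  )
  expect_identical(res2$runs$rmse_time,
                   res$runs$rmse_time[res$runs$variant == "BMT"])
})
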