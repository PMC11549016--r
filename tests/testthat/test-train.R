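make_toy <- function(n = 40, seed = 51) {
  generate_synthetic(synthetic_spec(n / 2, n / 2, length = 21,
                                    motif_rate = 0.8, seed = seed))
}

test_that("training descends the loss on a separable toy problem", {
  recs <- make_toy()
  sp <- split_dataset(recs, c(3, 1), seed = 1)
  res <- train_fold(sp$train, sp$test, tiny_config(),
                    train_config(epochs = 4, batch_size = 16), seed = 2)
  expect_lt(res$history[4], res$history[1])
  expect_true(all(is.finite(res$history)))
})

test_that("training is deterministic under a fixed seed", {
  recs <- make_toy(seed = 52)
  sp <- split_dataset(recs, c(3, 1), seed = 1)
  tc <- train_config(epochs = 2, batch_size = 16)
  r1 <- train_fold(sp$train, sp$test, tiny_config(), tc, seed = 7)
  r2 <- train_fold(sp$train, sp$test, tiny_config(), tc, seed = 7)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$history, r2$history)
  expect_identical(predict_proba(r1$checkpoint, sp$test),
                   predict_proba(r2$checkpoint, sp$test))
})

test_that("train_fold rejects invalid splits", {
  recs <- make_toy(seed = 53)
  expect_error(train_fold(recs, recs, tiny_config(), train_config()),
               "overlap")
  one <- recs[recs$label == 1, ]
  other <- recs[recs$label == 0, ]
  expect_error(train_fold(one, other, tiny_config(), train_config()),
               "both classes")
  expect_error(train_fold(recs[0, ], recs, tiny_config(), train_config()),
               "empty")
})

test_that("adversarial training adds the perturbed loss term and still runs", {
  recs <- make_toy(seed = 54)
  sp <- split_dataset(recs, c(3, 1), seed = 1)
  res <- train_fold(sp$train, sp$test, tiny_config(),
                    train_config(epochs = 2, batch_size = 16),
                    fgm = fgm_config(epsilon = 0.1,
                                     mode = "adversarial-train"), seed = 3)
  expect_true(all(is.finite(unlist(res$metrics))))
})

test_that("cross-validation yields one metric row per fold and exact means", {
  recs <- make_toy(n = 30, seed = 55)
  cv <- cross_validate(recs, k = 3, config = tiny_config(),
                       tconfig = train_config(epochs = 1, batch_size = 16,
                                              seed = 5))
  expect_equal(nrow(cv$folds), 3)
  expect_equal(cv$folds$fold, 1:3)
  mean_row <- cv$summary[cv$summary$stat == "mean", ]
  expect_equal(mean_row$ACC, mean(cv$folds$ACC), tolerance = 1e-12)
  expect_equal(mean_row$AUROC, mean(cv$folds$AUROC), tolerance = 1e-12)
})

test_that("checkpoints round-trip through disk with identical predictions", {
  recs <- make_toy(seed = 56)
  sp <- split_dataset(recs, c(3, 1), seed = 1)
  res <- train_fold(sp$train, sp$test, tiny_config(),
                    train_config(epochs = 1, batch_size = 16), seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(res$checkpoint, f)
  back <- load_checkpoint(f)
  expect_identical(predict_proba(back, sp$test),
                   predict_proba(res$checkpoint, sp$test))
  raw <- readRDS(f)
  raw$format_version <- "0.0"
  saveRDS(raw, f)
  expect_error(load_checkpoint(f), "version")
})

test_that("the ablation harness runs requested cells with correct inventories", {
  recs <- make_toy(n = 24, seed = 57)
  ab <- run_ablation(recs, grid = c("onehot", "integer", "pseknc"),
                     k = 2, config = tiny_config(),
                     tconfig = train_config(epochs = 1, batch_size = 12),
                     keep_checkpoints = TRUE)
  expect_equal(nrow(ab$table), 3)
  expect_equal(ab$table$cell, c("onehot", "integer", "pseknc"))
  # single-path cells never construct the other path's parameters
  p_int <- ab$runs[["integer"]]$checkpoints[[1]]$params
  expect_null(p_int$conv)
  expect_false(is.null(p_int$gru))
  p_pse <- ab$runs[["pseknc"]]$checkpoints[[1]]$params
  expect_null(p_pse$gru)
  expect_false(is.null(p_pse$conv))
  expect_error(run_ablation(recs, grid = "nonsense"), "cell|grid|TRUE")
})
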