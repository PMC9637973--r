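small_ds <- function(n = 8, seed = 17) {
  generate_dataset(phantom_params(height = 32, width = 32, arc_thickness = 3,
                                  n_arcs = 1, seed = seed), n)
}

test_that("zero epochs returns the initialization unchanged", {
  ds <- small_ds(4)
  mc <- tiny_model_config(base_channels = 4, attention_channels = 8)
  tc <- train_config(epochs = 0, seed = 2, holdout_frac = 0)
  fit <- train_ugbnet(ds, mc, tc)
  expect_identical(fit$weights, init_ugbnet(mc, seed = 2))
  expect_equal(nrow(fit$history), 0)
})

test_that("training is deterministic under a fixed seed", {
  ds <- small_ds(6)
  mc <- tiny_model_config(base_channels = 4, attention_channels = 8)
  tc <- train_config(epochs = 2, batch_size = 4, seed = 9, holdout_frac = 0)
  f1 <- train_ugbnet(ds, mc, tc)
  f2 <- train_ugbnet(ds, mc, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
})

test_that("a short seeded run reduces the training loss", {
  ds <- small_ds(8)
  mc <- tiny_model_config(base_channels = 8, attention_channels = 16)
  tc <- train_config(epochs = 15, batch_size = 8, seed = 5, holdout_frac = 0,
                     eval_every = 15)
  fit <- train_ugbnet(ds, mc, tc)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
})

test_that("training refuses samples without masks", {
  ds <- small_ds(4)
  ds[[2]]$mask <- NULL
  expect_error(train_ugbnet(ds, tiny_model_config(), train_config()), "mask")
})

test_that("fold assignment partitions every dataset size", {
  for (n in c(4, 8, 9, 11, 23)) {
    for (k in c(2, 4)) {
      lab <- fold_assignment(n, k, seed = n + k)
      expect_equal(sort(unique(lab)), seq_len(k))       # coverage
      expect_equal(length(lab), n)
      sizes <- table(lab)
      expect_lte(max(sizes) - min(sizes), 1)            # near-equal
    }
  }
  expect_error(fold_assignment(3, 4), "at least")
})

test_that("an oracle model scores 100.0 +/- 0.0 on all four metrics", {
  ds <- small_ds(8)
  tc <- train_config(folds = 4, seed = 3)
  cv <- cross_validate(ds, tiny_model_config(), tc,
                       model_factory = oracle_model_factory)
  expect_equal(cv$aggregate$mean, rep(1, 4))
  expect_equal(cv$aggregate$sd, rep(0, 4))
  tab <- format_cv_table(cv)
  expect_equal(tab$value, rep("100.0 ± 0.0", 4))
  # every sample appears in exactly one test fold, folds of size 2
  expect_equal(sort(cv$per_image$id), sort(vapply(ds, `[[`, character(1), "id")))
  expect_equal(unname(table(cv$per_image$fold)), rep(2L, 4), ignore_attr = TRUE)
})

test_that("a constant all-background model scores zero Dice", {
  ds <- small_ds(8)
  tc <- train_config(folds = 4, seed = 3)
  cv <- cross_validate(ds, tiny_model_config(), tc,
                       model_factory = constant_model_factory(0))
  expect_equal(cv$aggregate$mean[cv$aggregate$metric == "dice"], 0)
})

test_that("no test-fold sample ever reaches a fold's training set", {
  ds <- small_ds(9)
  tc <- train_config(folds = 4, seed = 8)
  seen <- list()
  spy_factory <- function(train_samples, model_cfg, train_cfg) {
    seen[[length(seen) + 1]] <<- vapply(train_samples, `[[`, character(1), "id")
    function(sample) sample$mask + 0
  }
  cv <- cross_validate(ds, tiny_model_config(), tc, model_factory = spy_factory)
  for (f in seq_len(4)) {
    test_ids <- cv$per_image$id[cv$per_image$fold == f]
    expect_length(intersect(seen[[f]], test_ids), 0)
    expect_setequal(c(seen[[f]], test_ids), vapply(ds, `[[`, character(1), "id"))
  }
})

test_that("tidy, glance and autoplot work on fits and cross-validations", {
  ds <- small_ds(4)
  mc <- tiny_model_config(base_channels = 4, attention_channels = 8)
  fit <- train_ugbnet(ds, mc, train_config(epochs = 1, batch_size = 4,
                                           seed = 1, holdout_frac = 0))
  expect_named(tidy(fit), c("epoch", "loss", "dice"))
  g <- glance(fit)
  expect_equal(g$epochs, 1)
  expect_gt(g$n_parameters, 1000)
  expect_s3_class(autoplot(fit), "ggplot")
  cv <- cross_validate(ds, mc, train_config(folds = 2, seed = 1),
                       model_factory = oracle_model_factory)
  expect_named(tidy(cv), c("fold", "metric", "value"))
  expect_equal(nrow(glance(cv)), 1)
  expect_s3_class(autoplot(cv), "ggplot")
  pred <- predict(fit, ds[1:2], type = "mask")
  expect_named(pred, c("id", "prob", "mask"))
  expect_true(all(pred$mask[[1]] %in% c(0, 1)))
})
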