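test_that("early stopping fires at best_epoch + patience and restores the best weights", {
  ds <- tiny_dataset(n = 16, L = 12, seed = 51)
  tr <- dataset_tensors(ds, ds$split$train_idx)
  va <- dataset_tensors(ds, ds$split$val_idx)
  mod <- build_model(tiny_model_config(L = 12), seed = 51)

  # injected monitor: peak at epoch 5, strictly decreasing afterwards;
  # the closure also snapshots the weights the monitor saw each epoch
  snapshots <- list()
  inj <- function(model, val_data, epoch) {
    snapshots[[epoch]] <<- model$params
    if (epoch <= 5) epoch else 5 - epoch * 0.01
  }
  cfg <- train_config(max_epochs = 40, patience = 6, batch_size = 8, seed = 1)
  fit <- train_network(mod, tr, va, cfg, monitor_fn = inj)
  expect_identical(fit$best_epoch, 5L)
  expect_identical(fit$stopped_epoch, 11L)           # best + patience
  expect_identical(fit$model$params, snapshots[[5]])  # epoch-5 checkpoint returned

  # plateau does not reset patience: strict-improvement semantics
  flat <- function(model, val_data, epoch) if (epoch == 1) 1 else 1
  fit2 <- train_network(mod, tr, va,
                        train_config(max_epochs = 30, patience = 4, batch_size = 8, seed = 1),
                        monitor_fn = flat)
  expect_identical(fit2$best_epoch, 1L)
  expect_identical(fit2$stopped_epoch, 5L)
})

test_that("an ever-improving monitor runs to max_epochs", {
  ds <- tiny_dataset(n = 12, L = 12, seed = 52)
  mod <- build_model(tiny_model_config(L = 12), seed = 52)
  fit <- train_network(mod, dataset_tensors(ds, ds$split$train_idx),
                       dataset_tensors(ds, ds$split$val_idx),
                       train_config(max_epochs = 7, patience = 3, batch_size = 8, seed = 2),
                       monitor_fn = function(model, val_data, epoch) epoch)
  expect_identical(fit$stopped_epoch, 7L)
  expect_identical(fit$best_epoch, 7L)
  expect_identical(nrow(fit$history), 7L)
})

test_that("training reduces the loss on a separable synthetic dataset", {
  ds <- tiny_dataset(n = 60, L = 16, seed = 53)
  tr <- dataset_tensors(ds, ds$split$train_idx)
  va <- dataset_tensors(ds, ds$split$val_idx)
  mod <- build_model(tiny_model_config(L = 16), seed = 53)
  fit <- train_network(mod, tr, va,
                       train_config(learning_rate = 0.1, max_epochs = 12,
                                    patience = 11, batch_size = 16, seed = 3))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_true(all(diff(fit$history$epoch) == 1))
  expect_lte(fit$best_epoch, fit$stopped_epoch)
})

test_that("best-checkpoint restoration reproduces the recorded monitor value", {
  ds <- tiny_dataset(n = 40, L = 12, seed = 54)
  tr <- dataset_tensors(ds, ds$split$train_idx)
  va <- dataset_tensors(ds, ds$split$val_idx)
  mod <- build_model(tiny_model_config(L = 12), seed = 54)
  fit <- train_network(mod, tr, va,
                       train_config(learning_rate = 0.05, max_epochs = 6,
                                    patience = 5, batch_size = 8, seed = 4))
  re_acc <- epoch_accuracy(predict(fit$model, va$x), va$y)
  expect_equal(re_acc, fit$best_monitor, tolerance = 1e-6)
})

test_that("training is reproducible for a fixed seed", {
  ds <- tiny_dataset(n = 24, L = 12, seed = 55)
  tr <- dataset_tensors(ds, ds$split$train_idx)
  va <- dataset_tensors(ds, ds$split$val_idx)
  cfg <- train_config(max_epochs = 3, patience = 2, batch_size = 8, seed = 9)
  f1 <- train_network(build_model(tiny_model_config(L = 12), seed = 5), tr, va, cfg)
  f2 <- train_network(build_model(tiny_model_config(L = 12), seed = 5), tr, va, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("epoch_accuracy equals top-1 accuracy and guards apply", {
  set.seed(56)
  sc <- rmat(30, 4)
  y <- matrix(rbinom(120, 1, 0.4), 30, 4)
  y[rowSums(y) == 0, 2] <- 1
  expect_equal(epoch_accuracy(sc, y), top_k_accuracy(sc, y, 1, warn = FALSE))
  expect_equal(epoch_accuracy(y, y), 1.0)

  ds <- tiny_dataset(n = 10, L = 12, seed = 57)
  mod <- build_model(tiny_model_config(L = 12), seed = 57)
  expect_error(
    train_network(mod, dataset_tensors(ds), NULL, train_config(max_epochs = 2, patience = 1)),
    "validation set is empty"
  )
  expect_error(train_config(patience = 30, max_epochs = 20), "patience")
})
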