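## a small capsule configuration keeps these bookkeeping tests fast
small_cfg <- function(...) {
  capsnet_config(conv_channels = 2, primary_channels = 4, primary_dim = 2,
                 mi_dim = 3, decoder_sizes = c(16, 16, 588), ...)
}

test_that("one epoch on one batch yields one update and one history row", {
  im <- make_image_fixture(25, seed = 21)   # 50 images = exactly one batch
  m <- train_model(im, model_cfg = small_cfg(),
                   train_cfg = train_config(epochs = 1, batch_size = 50,
                                            seed = 3))
  expect_equal(nrow(m$history), 1)
  expect_named(m$history,
               c("epoch", "train_loss", "train_acc", "val_loss", "val_acc"))
  expect_true(is.finite(m$history$train_loss))
})

test_that("training is bit-reproducible for a fixed seed", {
  im <- make_image_fixture(5, seed = 22)
  tc <- train_config(epochs = 3, batch_size = 5, seed = 99)
  m1 <- train_model(im, model_cfg = small_cfg(), train_cfg = tc)
  m2 <- train_model(im, model_cfg = small_cfg(), train_cfg = tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("SGD reduces the training loss on a strong-effect fixture", {
  im <- make_image_fixture(30, seed = 23)   # 60 high-SNR images
  m <- train_model(im, model_cfg = small_cfg(),
                   train_cfg = train_config(epochs = 50, batch_size = 20,
                                            seed = 5))
  expect_lt(m$history$train_loss[50], m$history$train_loss[1])
})

test_that("evaluate computes 1 - misclassification with complement symmetry", {
  im <- make_image_fixture(10, seed = 24)
  m <- train_model(im, model_cfg = small_cfg(),
                   train_cfg = train_config(epochs = 5, batch_size = 10,
                                            seed = 6))
  acc <- evaluate(m, im)
  acc_flip <- evaluate(m, im, y = 1L - im$labels)
  expect_equal(acc + acc_flip, 1)
  expect_true(acc >= 0 && acc <= 1)
  pred <- predict(m, im)
  expect_equal(mean(pred == im$labels), acc)
  expect_error(evaluate(m, im, y = integer(0)), "empty")
})

test_that("the early-stopping monitor reproduces hand-traced decisions", {
  ## strictly decreasing: never stops
  mon <- early_stop_monitor(c(5, 4, 3, 2, 1), patience = 1)
  expect_false(mon$stop)
  expect_equal(mon$best_epoch, 5)

  ## constant: stops after epoch 4 with best epoch 1
  mon2 <- early_stop_monitor(rep(1, 10), patience = 3)
  expect_true(mon2$stop)
  expect_equal(mon2$best_epoch, 1)
  expect_equal(mon2$wait, 3)

  ## hand trace: (1.0, 0.8, 0.9, 0.7), patience 2: no stop, best epoch 4
  mon3 <- early_stop_monitor(c(1.0, 0.8, 0.9, 0.7), patience = 2)
  expect_false(mon3$stop)
  expect_equal(mon3$best_epoch, 4)

  expect_error(early_stop_monitor(c(1, 2), patience = 0), "patience")
})

test_that("early stopping halts training and returns best-epoch weights", {
  im <- make_image_fixture(15, seed = 25)
  tc <- train_config(epochs = 40, batch_size = 10, seed = 7,
                     early_stopping = TRUE, patience = 3,
                     validation_fraction = 0.2)
  m <- train_model(im, model_cfg = small_cfg(), train_cfg = tc)
  expect_true(nrow(m$history) <= 40)
  expect_true(!is.null(m$best_epoch))
  expect_true(all(is.finite(m$history$val_loss)))
  expect_equal(m$best_epoch, which.min(m$history$val_loss))
})

test_that("grid search ranks configurations and skips invalid points", {
  im_tr <- make_image_fixture(10, seed = 26)
  im_te <- make_image_fixture(10, seed = 27)
  tc <- train_config(epochs = 3, batch_size = 10, seed = 8)

  g1 <- grid_spec(routing_iters = 1, reconstruction = TRUE,
                  conv_channels = 2, primary_channels = 4,
                  primary_dim = 2, mi_dim = 3)
  r1 <- grid_search(g1, im_tr, im_te, tc)
  expect_equal(nrow(r1), 1)
  cfg1 <- capsnet_config(conv_channels = 2, primary_channels = 4,
                         primary_dim = 2, mi_dim = 3, routing_iters = 1)
  m1 <- train_model(im_tr, model_cfg = cfg1, train_cfg = tc)
  expect_equal(r1$accuracy[1], evaluate(m1, im_te))

  g2 <- grid_spec(routing_iters = 1:2, reconstruction = FALSE,
                  conv_channels = 2, primary_channels = 2,
                  primary_dim = 2, mi_dim = 2)
  r2 <- grid_search(g2, im_tr, im_te, tc)
  expect_equal(nrow(r2), 2)
  expect_true(all(r2$status == "ok"))
  expect_true(all(diff(r2$accuracy) <= 0))  # sorted descending

  ## the reconstruction on/off comparison pairs matched configurations
  g4 <- grid_spec(routing_iters = 1, reconstruction = c(TRUE, FALSE),
                  conv_channels = 2, primary_channels = 2,
                  primary_dim = 2, mi_dim = 2)
  r4 <- grid_search(g4, im_tr, im_te, tc)
  eff <- reconstruction_effect(r4)
  expect_equal(nrow(eff), 1)
  expect_equal(eff$effect, eff$acc_with - eff$acc_without)

  ## an unbuildable grid point is recorded, not fatal
  g3 <- rbind(g2, data.frame(routing_iters = 0, reconstruction = FALSE,
                             conv_channels = 2, primary_channels = 2,
                             primary_dim = 2, mi_dim = 2))
  expect_warning(r3 <- grid_search(g3, im_tr, im_te, tc), "skipped")
  expect_equal(nrow(r3), 3)
  expect_equal(sum(is.na(r3$accuracy)), 1)
})

test_that("training rejects empty data and mismatched labels", {
  im <- make_image_fixture(2, seed = 28)
  expect_error(train_model(matrix(0, 588, 0), integer(0),
                           model_cfg = small_cfg(),
                           train_cfg = train_config(epochs = 1)),
               "empty|labels")
  expect_error(train_model(im, y = c(0L, 1L), model_cfg = small_cfg(),
                           train_cfg = train_config(epochs = 1)),
               "labels")
})
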