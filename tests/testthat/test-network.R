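test_that("built graph has the documented shapes and parameter counts", {
  cfg <- model_config(input_rows = 21, input_cols = 12, n_channels = 9,
                      filter_heights = 5, filters_per_channel = 32,
                      pool_size = Inf)
  model <- build_model(cfg)

  # concatenated feature length under global max pooling: 9 channels x 32
  expect_equal(nrow(model$params$W1), 9L * 32L)

  # local pooling: conv output length 17, pool 2 -> 8 blocks per filter
  cfg2 <- model_config(input_rows = 21, input_cols = 12, n_channels = 9,
                       filter_heights = 5, filters_per_channel = 32,
                       pool_size = 2)
  expect_equal(nrow(build_model(cfg2)$params$W1), 9L * 8L * 32L)

  # conv layer: (height * width * 1 + 1) * filters = (5*12 + 1) * 32
  counts <- parameter_counts(model)
  conv1 <- sum(counts$parameters[counts$layer %in% c("convW1", "convb1")])
  expect_equal(conv1, (5L * 12L + 1L) * 32L)  # 1952

  # output layer: exactly 2 units
  expect_equal(ncol(model$params$W2), 2L)
  expect_length(model$params$b2, 2L)

  expect_error(model_config(input_rows = 21, input_cols = 12,
                            filter_heights = 22), "filter heights")
  expect_error(model_config(input_rows = 21, input_cols = 12,
                            dropout_p = 1), "dropout")
})

test_that("softmax probabilities normalize and argmax sets hard labels", {
  fit <- shared_tiny_fit()
  pred <- predict(fit$model, fit$eval)
  expect_true(all(abs(pred$p_negative + pred$p_positive - 1) < 1e-9))
  expect_equal(pred$label, as.integer(pred$p_positive >= pred$p_negative))

  # both alphabet widths are accepted by a matching config
  ds <- random_windows(4L, 8L, seed = 9L)
  encm <- encode_dataset(ds, "merged", structures = fold_windows(ds))
  cfgm <- tiny_config(rows = 17L, cols = 12L)
  pm <- predict(train_cnn(build_model(cfgm), encm, validation = encm), encm)
  expect_true(all(abs(pm$p_negative + pm$p_positive - 1) < 1e-9))

  # shape contract
  expect_error(predict(fit$model, encm), "shape")

  # empty batch -> empty output
  empty <- fit$eval$x[0, , , drop = FALSE]
  expect_equal(nrow(predict(fit$model, empty)), 0L)
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(input_rows = 9, input_cols = 4, n_channels = 2,
                      filter_heights = c(2, 3), filters_per_channel = 2,
                      dense_units = 5, dropout_p = 0, learning_rate = 1e-3,
                      seed = 99)
  model <- build_model(cfg)
  ds <- random_windows(4L, 4L, seed = 21L)
  enc <- encode_dataset(ds, "general")
  Y <- psiCNN:::one_hot_labels(enc$y)
  heights <- unique(cfg$filter_heights)
  hmap <- match(cfg$filter_heights, heights)
  cols <- lapply(heights, function(h) psiCNN:::im2col(enc$x, h))
  n <- length(enc$y)

  loss_of <- function(params) {
    fwd <- psiCNN:::cnn_forward(params, cfg, cols, hmap, n)
    -mean(log(pmax(fwd$probs, 1e-12))[Y == 1])
  }
  fwd <- psiCNN:::cnn_forward(model$params, cfg, cols, hmap, n)
  grads <- psiCNN:::cnn_backward(model$params, cfg, cols, hmap, n, fwd, Y,
                                 dropout_mask = NULL)

  eps <- 1e-6
  withr::with_seed(5, {
    for (nm in names(model$params)) {
      for (rep in 1:3) {
        k <- sample(length(model$params[[nm]]), 1)
        up <- model$params; up[[nm]][k] <- up[[nm]][k] + eps
        dn <- model$params; dn[[nm]][k] <- dn[[nm]][k] - eps
        numeric_grad <- (loss_of(up) - loss_of(dn)) / (2 * eps)
        expect_equal(grads[[nm]][k], numeric_grad, tolerance = 1e-4,
                     label = paste("grad", nm, "entry", k))
      }
    }
  })
})

test_that("training is deterministic under a fixed seed", {
  ds <- random_windows(30L, 6L, seed = 13L)
  enc <- encode_dataset(ds, "general")
  cfg <- tiny_config(rows = 13L, cols = 4L)
  cfg$max_epochs <- 5L
  fit1 <- train_cnn(build_model(cfg), enc)
  fit2 <- train_cnn(build_model(cfg), enc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
})

test_that("separable synthetic data trains well above the chance level", {
  fit <- shared_tiny_fit()
  pred <- predict(fit$model, fit$eval)
  acc <- mean(pred$label == fit$eval$y)
  expect_gt(acc, 0.5)   # balanced generator; chance = 0.5
  expect_gt(acc, 0.8)
})

test_that("degenerate single-class training warns", {
  ds <- random_windows(10L, 5L, seed = 17L)
  enc <- encode_dataset(ds, "general")
  enc$y <- rep(1L, 10L)
  cfg <- tiny_config(rows = 11L, cols = 4L)
  cfg$max_epochs <- 1L
  expect_warning(train_cnn(build_model(cfg), enc, validation = enc),
                 "one class")
  expect_error(train_cnn(build_model(cfg),
                         list(x = enc$x[0, , , drop = FALSE], y = integer())),
               "empty")
})

test_that("training history, tidy/glance and save/load behave", {
  fit <- shared_tiny_fit()$model
  expect_true(all(c("epoch", "loss", "accuracy", "val_loss", "val_accuracy")
                  %in% names(fit$history)))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$parameters), sum(lengths(fit$params)))
  gl <- glance(fit)
  expect_true(gl$trained)
  expect_equal(gl$best_epoch, fit$best_epoch)

  f <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, f)
  back <- load_model(f)
  expect_identical(back$params, fit$params)
})
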