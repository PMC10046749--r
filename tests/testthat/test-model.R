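test_that("the reference geometry halves 224 through each of four blocks", {
  model <- build_cnn(cnn_config())
  trace <- model$shape_trace
  expect_true(any(grepl("b1 maxpool(2x2): 112x112x64", trace, fixed = TRUE)))
  expect_true(any(grepl("b2 maxpool(2x2): 56x56x64", trace, fixed = TRUE)))
  expect_true(any(grepl("b3 maxpool(2x2): 28x28x64", trace, fixed = TRUE)))
  expect_true(any(grepl("b4 maxpool(2x2): 14x14x64", trace, fixed = TRUE)))
  expect_true(any(grepl("flatten: 12544", trace, fixed = TRUE)))
  # stride-1 convolutions preserve the spatial size under same padding
  expect_true(any(grepl("b1c1 conv(3x3, stride 1): 224x224x64", trace,
                        fixed = TRUE)))
})

test_that("stride-2 convolutions collapse four blocks and are rejected", {
  err <- expect_error(
    build_cnn(cnn_config(conv_stride = 2)),
    "collapsed below 1x1")
  # the error carries the layer-by-layer trace
  expect_match(conditionMessage(err), "conv\\(3x3, stride 2\\)")
  # with fewer blocks the stride-2 variant is geometrically fine
  expect_s3_class(build_cnn(cnn_config(conv_stride = 2, n_blocks = 2)),
                  "cnn_model")
})

test_that("a zero image through a zeroed output layer scores exactly 0.5", {
  model <- build_cnn(small_cnn_config(seed = 1))
  model$params$fc2_W[] <- 0
  model$params$fc2_b[] <- 0
  p <- predict_cnn(model, array(0, c(16, 16, 3)))
  expect_identical(p, 0.5)
})

test_that("prediction is a pure function with probabilities in [0, 1]", {
  model <- build_cnn(small_cnn_config(seed = 2))
  set.seed(30)
  imgs <- array(runif(16 * 16 * 3 * 5), c(16, 16, 3, 5))
  p_batch <- predict_cnn(model, imgs)
  expect_length(p_batch, 5)
  expect_true(all(p_batch >= 0 & p_batch <= 1))
  p_single <- vapply(1:5, function(i) predict_cnn(model, imgs[, , , i]),
                     numeric(1))
  expect_equal(p_batch, p_single)  # dropout off: batch == singles
  expect_identical(predict_cnn(model, imgs[, , , 1]),
                   predict_cnn(model, imgs[, , , 1]))
  expect_error(predict_cnn(model, array(0, c(8, 8, 3))), "images must be")
})

test_that("training starts near ln(2) and stops at exactly the patience", {
  cfg <- small_cnn_config(seed = 3, learning_rate = 0, max_epochs = 30,
                          validation_patience = 4, batch_size = 8)
  model <- build_cnn(cfg)
  model$params$fc2_W[] <- 0
  model$params$fc2_b[] <- 0
  set.seed(31)
  imgs <- array(runif(16 * 16 * 3 * 20), c(16, 16, 3, 20))
  labels <- rep(c(0, 1), 10)
  trained <- train_cnn(model, imgs, labels)
  # lr = 0 keeps every output at 0.5: balanced BCE is ln 2 every epoch...
  expect_equal(trained$history$train_loss[1], log(2), tolerance = 1e-10)
  # ...so the frozen validation loss triggers early stopping at epoch
  # 1 + patience
  expect_equal(nrow(trained$history), 1 + cfg$validation_patience)
  expect_equal(trained$best_epoch, 1)
})

test_that("the network overfits a small separable set to 100% accuracy", {
  set.seed(32)
  imgs <- c(lapply(1:5, function(i) ridge_image(3)),
            lapply(1:5, function(i) ridge_image(12)))
  labels <- rep(c(0, 1), each = 5)
  cfg <- small_cnn_config(seed = 4, optimizer = "rmsprop",
                          learning_rate = 1e-3, max_epochs = 50,
                          batch_size = 5)
  trained <- train_cnn(build_cnn(cfg), imgs, labels, val_frac = 0)
  p <- predict_cnn(trained, imgs)
  expect_equal(mean((p >= 0.5) == labels), 1)
})

test_that("training is deterministic under a fixed seed and rejects one class", {
  set.seed(33)
  imgs <- array(runif(16 * 16 * 3 * 8), c(16, 16, 3, 8))
  labels <- rep(c(0, 1), 4)
  cfg <- small_cnn_config(seed = 5, max_epochs = 2, batch_size = 4)
  t1 <- train_cnn(build_cnn(cfg), imgs, labels)
  t2 <- train_cnn(build_cnn(cfg), imgs, labels)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$history, t2$history)
  expect_error(train_cnn(build_cnn(cfg), imgs, rep(1, 8)), "both classes")
})

test_that("each optimizer reduces the training loss on a separable set", {
  set.seed(34)
  imgs <- c(lapply(1:6, function(i) ridge_image(3)),
            lapply(1:6, function(i) ridge_image(12)))
  labels <- rep(c(0, 1), each = 6)
  for (opt in c("adam", "rmsprop", "sgdm")) {
    cfg <- small_cnn_config(seed = 6, optimizer = opt, learning_rate = 1e-3,
                            max_epochs = 12, batch_size = 6)
    trained <- train_cnn(build_cnn(cfg), imgs, labels, val_frac = 0)
    expect_lt(tail(trained$history$train_loss, 1),
              trained$history$train_loss[1])
  }
})

test_that("noise augmentation doubles the set and is seeded", {
  set.seed(35)
  imgs <- array(runif(4 * 4 * 3 * 6, 0.2, 0.8), c(4, 4, 3, 6))
  labels <- rep(c(0, 1), 3)
  aug <- augment_with_noise(imgs, labels, augment_config(seed = 7))
  expect_equal(dim(aug$images)[4], 12)
  expect_equal(aug$labels, c(labels, labels))
  expect_identical(aug$images[, , , 1:6], imgs)   # originals retained
  expect_true(all(aug$images >= 0 & aug$images <= 1))
  # noise has positive mean: copies are brighter on average
  expect_gt(mean(aug$images[, , , 7:12]), mean(imgs))

  aug2 <- augment_with_noise(imgs, labels, augment_config(seed = 7))
  expect_identical(aug$images, aug2$images)
  aug3 <- augment_with_noise(imgs, labels, augment_config(seed = 8))
  expect_false(identical(aug$images, aug3$images))

  silent <- augment_with_noise(imgs, labels,
                               augment_config(noise_mean_frac = 0,
                                              noise_sd_frac = 0))
  expect_equal(silent$images[, , , 7:12], imgs, tolerance = 1e-15)

  triple <- augment_with_noise(imgs, labels, augment_config(copies = 2))
  expect_equal(dim(triple$images)[4], 18)
})
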