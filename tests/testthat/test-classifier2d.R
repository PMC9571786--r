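# tiny planted-ridge images: class A carries a bright vertical stripe on
# the left third, class B on the right third
ridge_images <- function(n_per_class, size = 64L, seed = 1) {
  set.seed(seed)
  make <- function(left) {
    img <- array(stats::runif(size * size * 3, 0, 0.1), c(size, size, 3L))
    cols <- if (left) 8:14 else (size - 14):(size - 8)
    img[, cols, ] <- img[, cols, ] + 0.8
    img
  }
  imgs <- c(lapply(seq_len(n_per_class), function(i) make(TRUE)),
            lapply(seq_len(n_per_class), function(i) make(FALSE)))
  list(images = imgs, labels = rep(c("A", "B"), each = n_per_class))
}

test_that("backbones build with the right head and reject unknown names", {
  m <- build_transfer_model(base_width = 4L, n_classes = 2L, seed = 1)
  E <- asNamespace("ramangrade")
  x <- array(stats::rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  z <- E$nn_forward(m$net, x, training = FALSE)
  expect_equal(dim(z), c(1L, 2L))
  m3 <- build_transfer_model(base_width = 4L, n_classes = 3L, seed = 1)
  expect_equal(dim(E$nn_forward(m3$net, x, FALSE)), c(1L, 3L))
  expect_error(build_transfer_model("vgg"), class = "ramangrade_validation")
  expect_error(build_transfer_model(pretrained = TRUE),
               class = "ramangrade_validation")
})

test_that("eval-mode forwards are deterministic, train-mode reproducible by seed", {
  E <- asNamespace("ramangrade")
  m <- build_transfer_model(base_width = 4L, seed = 3)
  x <- array(stats::rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  expect_identical(E$nn_forward(m$net, x, FALSE), E$nn_forward(m$net, x, FALSE))
  # dropout active in training mode, but reproducible under one seed
  set.seed(11); a <- E$nn_forward(m$net, x, TRUE)
  set.seed(11); b <- E$nn_forward(m$net, x, TRUE)
  expect_identical(a, b)
})

test_that("image augmentation respects the 2% crop bound and its seed", {
  img <- array(stats::runif(224 * 224 * 3), c(224, 224, 3))
  cfg <- image_augment_config()
  expect_equal(floor(0.02 * 224), 4)
  # crop-only augmentation: a pixel further than 4 rows/cols from every
  # image structure can only move by the allowed offset; probe with a
  # single bright pixel and locate it after many draws
  probe <- array(0, c(224, 224, 3)); probe[100, 100, ] <- 1
  cfg_crop <- image_augment_config(gauss_noise_sigma = 0,
                                   sharpness_range = c(1, 1))
  set.seed(2)
  for (i in 1:25) {
    out <- augment_image(probe, cfg_crop)
    hot <- which(out[, , 1] == max(out[, , 1]), arr.ind = TRUE)[1, ]
    expect_true(all(abs(hot - c(100, 100)) <= 5))
  }
  expect_identical(augment_image(img, cfg, seed = 7),
                   augment_image(img, cfg, seed = 7))
  # all magnitudes off -> pure per-image z-score of the input
  cfg0 <- image_augment_config(crop_max_frac = 0, gauss_noise_sigma = 0,
                               sharpness_range = c(1, 1))
  out <- augment_image(img, cfg0, seed = 1)
  expect_equal(out, (img - mean(img)) / stats::sd(as.vector(img)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(image_augment_config(crop_max_frac = 0.6),
               class = "ramangrade_validation")
})

test_that("training separates planted ridges and logs a falling loss", {
  rd <- ridge_images(12L, size = 64L, seed = 5)
  m <- build_transfer_model(base_width = 4L, n_classes = 2L, seed = 5)
  m <- train_2d(m, rd$images, rd$labels,
                train_config_2d(epochs = 4L, learning_rate = 2e-3,
                                batch_size = 8L, seed = 5,
                                augment = image_augment_config(resize_to = 64L)))
  pred <- predict_2d(m, rd$images)
  expect_equal(mean(pred$label == rd$labels), 1)
  expect_lt(m$history$loss[4], m$history$loss[1])
  expect_error(train_2d(build_transfer_model(base_width = 4L), rd$images,
                        rep("A", length(rd$images)),
                        train_config_2d(epochs = 1L)),
               class = "ramangrade_validation")
})

test_that("alternative backbones train end to end at smoke scale", {
  rd <- ridge_images(6L, size = 64L, seed = 6)
  for (bb in c("senet", "efficientnet")) {
    m <- build_transfer_model(bb, base_width = 4L, n_classes = 2L, seed = 6)
    m <- train_2d(m, rd$images, rd$labels,
                  train_config_2d(epochs = 1L, learning_rate = 1e-3,
                                  batch_size = 6L, seed = 6, augment = NULL))
    p <- predict_2d(m, rd$images[1:2])
    expect_equal(nrow(p), 2L)
    expect_true(all(is.finite(p$p_A)))
  }
})

test_that("predictions are normalized, order-invariant and tie-stable", {
  rd <- ridge_images(3L, size = 64L, seed = 8)
  m <- build_transfer_model(base_width = 4L, n_classes = 2L, seed = 8)
  m <- train_2d(m, rd$images, rd$labels,
                train_config_2d(epochs = 1L, learning_rate = 1e-3,
                                batch_size = 6L, seed = 8, augment = NULL))
  p <- predict_2d(m, rd$images)
  expect_equal(p$p_A + p$p_B, rep(1, nrow(p)), tolerance = 1e-6)
  p_rev <- predict_2d(m, rev(rd$images))
  expect_equal(rev(p_rev$p_A), p$p_A, tolerance = 1e-12)
  expect_error(predict_2d(m, list(array(0, c(8, 8)))),
               class = "ramangrade_validation")
  # equal logits resolve to the first (lowest-index) class
  E <- asNamespace("ramangrade")
  head_layer <- m$net$layers[[length(m$net$layers)]]
  head_layer$W[] <- 0; head_layer$b[] <- 0
  p0 <- predict_2d(m, rd$images[1])
  expect_equal(p0$label, "A")
})
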