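#' Build the stage-1 1D convolutional classifier
#'
#' A single 1D convolution (1 input channel, 4 output channels, kernel
#' length 6), max-pooling with kernel 3 and stride 3, then three fully
#' connected layers of 1024, 256 and 128 units, each followed by batch
#' normalization and ReLU, ending in a single logit (sigmoid applied at
#' prediction/loss time). The same body with a wider head serves as the
#' 1D CNN baseline in three-class mode.
#'
#' @param input_length Number of spectral points the model accepts.
#' @param n_out Output width: 1 (binary, default) or the number of classes.
#' @param conv_out_channels,conv_kernel,pool_kernel,pool_stride,fc_sizes
#'   Architecture knobs, defaulting to the published configuration.
#' @param seed Integer seed fixing the initial weights.
#' @return A `cnn1d` model object.
#' @export
build_cnn1d <- function(input_length, n_out = 1L,
                        conv_out_channels = 4L, conv_kernel = 6L,
                        pool_kernel = 3L, pool_stride = 3L,
                        fc_sizes = c(1024L, 256L, 128L), seed = 1L) {
  input_length <- as.integer(input_length)
  lo <- input_length - conv_kernel + 1L
  lp <- if (lo >= pool_kernel) (lo - pool_kernel) %/% pool_stride + 1L else 0L
  min_len <- conv_kernel + pool_kernel - 1L
  if (lp < 1L) {
    rlang::abort(sprintf(
      "input_length %d too short: conv+pool need at least %d points",
      input_length, min_len), class = "ramangrade_validation")
  }
  with_opt_seed(seed, {
    layers <- list(
      layer_conv1d(1L, conv_out_channels, conv_kernel),
      layer_relu(),
      layer_maxpool1d(pool_kernel, pool_stride),
      layer_flatten()
    )
    n_in <- lp * conv_out_channels
    for (h in fc_sizes) {
      layers <- c(layers, list(layer_dense(n_in, h), layer_bn(h), layer_relu()))
      n_in <- h
    }
    layers <- c(layers, list(layer_dense(n_in, n_out)))
    structure(list(net = nn_network(layers), input_length = input_length,
                   n_out = as.integer(n_out), conv_pool_length = lp,
                   seed = seed, trained = FALSE, task = NULL,
                   history = NULL),
              class = "cnn1d")
  })
}

#' @export
print.cnn1d <- function(x, ...) {
  cat(sprintf("<cnn1d> input %d, conv+pool length %d, %s, %d parameters%s\n",
              x$input_length, x$conv_pool_length,
              if (x$n_out == 1L) "binary head" else sprintf("%d-class head", x$n_out),
              n_params(x$net),
              if (x$trained) sprintf(", trained (%s)", x$task %||% "labels") else ""))
  invisible(x)
}

#' Training configuration for the 1D stage
#'
#' Published defaults: batch 32, learning rate 1e-4, Adam with betas
#' (0.9, 0.999) and eps 1e-8, weight decay 0.01, binary cross entropy.
#' Epoch count is a free choice (default 150). `noise_scale` and
#' `shift_s` control the on-the-fly augmentations.
#'
#' @param batch_size,learning_rate,betas,eps,weight_decay,epochs,seed
#'   Optimizer and loop settings.
#' @param noise_scale Peak-proportional noise scale per batch (0 disables).
#' @param shift_s Maximum spectral shift in grid steps (0 disables).
#' @return A `train_config_1d` list.
#' @export
train_config_1d <- function(batch_size = 32L, learning_rate = 1e-4,
                            betas = c(0.9, 0.999), eps = 1e-8,
                            weight_decay = 0.01, epochs = 150L, seed = 1L,
                            noise_scale = 0.05, shift_s = 5L) {
  stopifnot(batch_size > 0, learning_rate > 0, epochs >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, betas = betas, eps = eps,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 seed = as.integer(seed), noise_scale = noise_scale,
                 shift_s = as.integer(shift_s)),
            class = "train_config_1d")
}

#' Train the stage-1 binary classifier
#'
#' Minimizes binary cross entropy with Adam. Each epoch draws one pass of
#' class-balanced samples (weighted random sampler, inverse class
#' frequency) and applies the additive-noise and spectral-shift
#' augmentations on the fly. Spectra are expected normalized
#' ([normalize_spectra()]).
#'
#' @param model A [build_cnn1d()] model with `n_out = 1`.
#' @param train A `raman_spectra` set containing both task classes.
#' @param task A [binary_task()]; its positive class maps to label 1.
#' @param cfg A [train_config_1d()].
#' @param sampler_weights Optional per-spectrum sampling weights;
#'   defaults to [weighted_sampler_weights()] over the task labels.
#' @return The fitted model with `$history` (tibble epoch/loss).
#' @export
train_binary_1d <- function(model, train, task, cfg = train_config_1d(),
                            sampler_weights = NULL) {
  lab <- task_labels(task, train$meta$grade)
  keep <- !is.na(lab)
  train <- train[keep]; lab <- lab[keep]
  y <- as.numeric(lab == "positive")
  if (length(unique(y)) < 2L) {
    rlang::abort("training set must contain both task classes",
                 class = "ramangrade_validation")
  }
  if (ncol(train$intensities) != model$input_length) {
    rlang::abort("spectra length does not match model input_length",
                 class = "ramangrade_validation")
  }
  if (is.null(sampler_weights)) sampler_weights <- weighted_sampler_weights(lab)
  n <- length(y)
  with_opt_seed(cfg$seed, {
    history <- numeric(cfg$epochs)
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      order_idx <- sample.int(n, n, replace = TRUE, prob = sampler_weights)
      losses <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- order_idx[start:min(start + cfg$batch_size - 1L, n)]
        xb <- train[idx]
        if (cfg$noise_scale > 0) xb <- augment_noise(xb, cfg$noise_scale)
        if (cfg$shift_s > 0) xb <- augment_shift(xb, cfg$shift_s)
        x <- array(xb$intensities, c(length(idx), model$input_length, 1L))
        z <- nn_forward(model$net, x, training = TRUE)
        lo <- loss_bce_logits(z, y[idx])
        nn_backward(model$net, lo$grad)
        step <- step + 1L
        adam_step(model$net, step, cfg$learning_rate, cfg$betas, cfg$eps,
                  cfg$weight_decay)
        losses <- c(losses, lo$loss)
      }
      history[ep] <- mean(losses)
    }
    nn_clear_cache(model$net)
    model$trained <- TRUE
    model$task <- task$name
    model$positive_classes <- task$positive_classes
    model$history <- tibble::tibble(epoch = seq_len(cfg$epochs), loss = history)
    model
  })
}

#' Predict with the stage-1 classifier
#'
#' Probability of the positive (EG1) class per spectrum; the label is the
#' positive class when the probability is `>= threshold` (a probability of
#' exactly 0.5 at the default threshold therefore predicts positive).
#'
#' @param model A trained [build_cnn1d()] model (`n_out = 1`).
#' @param spectra A `raman_spectra` set on the model's input length.
#' @param threshold Decision threshold, default 0.5.
#' @return Tibble with `spectrum_id`, `probability`, `label`
#'   (`"positive"`/`"negative"`).
#' @export
predict_1d <- function(model, spectra, threshold = 0.5) {
  if (ncol(spectra$intensities) != model$input_length) {
    rlang::abort("spectra length does not match model input_length",
                 class = "ramangrade_validation")
  }
  x <- array(spectra$intensities,
             c(nrow(spectra$intensities), model$input_length, 1L))
  z <- as.vector(nn_forward(model$net, x, training = FALSE))
  p <- 1 / (1 + exp(-z))
  tibble::tibble(spectrum_id = spectra$meta$spectrum_id, probability = p,
                 label = ifelse(p >= threshold, "positive", "negative"))
}

#' @exportS3Method generics::tidy
tidy.cnn1d <- function(x, ...) {
  if (is.null(x$history)) tibble::tibble(epoch = integer(), loss = numeric())
  else x$history
}

#' @exportS3Method generics::glance
glance.cnn1d <- function(x, ...) {
  tibble::tibble(
    n_parameters = n_params(x$net),
    input_length = x$input_length,
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history) || nrow(x$history) == 0) NA_real_
                 else x$history$loss[nrow(x$history)]
  )
}
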