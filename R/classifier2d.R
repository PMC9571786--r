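#' Build the stage-2 residual image classifier
#'
#' An 18-layer residual network in the classic topology (7x7 stride-2
#' stem, 3x3 stride-2 max pool, four stages of two basic blocks with
#' channel doubling and stride-2 downsampling, global average pooling,
#' dropout, linear head), so a 224x224x3 input yields a 7x7 final feature
#' map — the property the class-activation maps rely on. `base_width`
#' scales all channel counts; 64 is the canonical width, smaller values
#' give CPU-trainable models with the same depth and topology. Two
#' alternative backbones are pluggable: `"senet"` adds squeeze-and-
#' excitation gates to every block, and `"efficientnet"` is a compact
#' compound-scaled variant (one SE block per stage at 1.25x width).
#' Weights are He-initialized; there is no pretrained-weight source in
#' this implementation, so transfer learning reduces to architecture
#' reuse (`pretrained = FALSE` is the only supported value and exists for
#' interface compatibility).
#'
#' @param backbone `"resnet18"` (default), `"senet"`, `"efficientnet"`.
#' @param n_classes Head width = number of task categories.
#' @param base_width Stem channel count (canonical 64).
#' @param dropout_p Dropout before the head (default 0.2).
#' @param pretrained Must be `FALSE`; kept so configs naming it parse.
#' @param seed Integer seed fixing the initial weights.
#' @return A `cnn2d` model object.
#' @export
build_transfer_model <- function(backbone = c("resnet18", "senet", "efficientnet"),
                                 n_classes = 2L, base_width = 64L,
                                 dropout_p = 0.2, pretrained = FALSE, seed = 1L) {
  if (is.character(backbone) && length(backbone) == 1L &&
      !backbone %in% c("resnet18", "senet", "efficientnet")) {
    rlang::abort(sprintf("unknown backbone '%s'", backbone),
                 class = "ramangrade_validation")
  }
  backbone <- match.arg(backbone)
  if (isTRUE(pretrained)) {
    rlang::abort("pretrained weights are not available; use pretrained = FALSE",
                 class = "ramangrade_validation")
  }
  w <- as.integer(base_width)
  se <- backbone == "senet"
  if (backbone == "efficientnet") {
    w <- as.integer(round(w * 1.25))
    blocks_per_stage <- 1L
    se <- TRUE
  } else {
    blocks_per_stage <- 2L
  }
  with_opt_seed(seed, {
    layers <- list(
      layer_conv2d(3L, w, 7L, 2L, 3L),
      layer_bn(w, dim2d = TRUE),
      layer_relu(),
      layer_maxpool2d(3L, 2L, 1L)
    )
    ch <- w
    for (stage in 1:4) {
      out_ch <- w * 2L^(stage - 1L)
      for (b in seq_len(blocks_per_stage)) {
        stride <- if (stage > 1L && b == 1L) 2L else 1L
        layers <- c(layers, list(layer_resblock(ch, out_ch, stride, se = se)))
        ch <- out_ch
      }
    }
    layers <- c(layers, list(layer_gap2d(), layer_dropout(dropout_p),
                             layer_dense(ch, n_classes)))
    structure(list(net = nn_network(layers), backbone = backbone,
                   n_classes = as.integer(n_classes), base_width = w,
                   input_size = 224L, feature_channels = ch, seed = seed,
                   trained = FALSE, class_levels = NULL, history = NULL),
              class = "cnn2d")
  })
}

#' @export
print.cnn2d <- function(x, ...) {
  cat(sprintf("<cnn2d:%s> width %d, %d classes, %d parameters%s\n",
              x$backbone, x$base_width, x$n_classes, n_params(x$net),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Training configuration for the 2D stage
#'
#' Published defaults: batch 64, learning rate 5e-7 (the fine-tuning
#' regime), same Adam parameters as the 1D stage. Models trained from
#' random initialization need a larger learning rate.
#'
#' @inheritParams train_config_1d
#' @param augment An [image_augment_config()], or `NULL` to disable.
#' @export
train_config_2d <- function(batch_size = 64L, learning_rate = 5e-7,
                            betas = c(0.9, 0.999), eps = 1e-8,
                            weight_decay = 0, epochs = 100L, seed = 1L,
                            augment = image_augment_config()) {
  stopifnot(batch_size > 0, learning_rate > 0, epochs >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, betas = betas, eps = eps,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 seed = as.integer(seed), augment = augment),
            class = "train_config_2d")
}

#' 2D augmentation settings
#'
#' Random crop with offsets up to 2% of each axis followed by a resize
#' back to 224, a sharpness adjustment (factor uniform in
#' `sharpness_range`), per-image z-score normalization, and additive
#' Gaussian noise (sd 0.1) on the normalized values.
#'
#' @param crop_max_frac Maximum crop offset as a fraction of the axis
#'   length, in `[0, 0.5)`.
#' @param resize_to Output side length.
#' @param gauss_noise_sigma Noise SD on z-scored pixel values.
#' @param sharpness_range Two-element range of the sharpness factor.
#' @export
image_augment_config <- function(crop_max_frac = 0.02, resize_to = 224L,
                                 gauss_noise_sigma = 0.1,
                                 sharpness_range = c(0.8, 1.2)) {
  if (crop_max_frac < 0 || crop_max_frac >= 0.5) {
    rlang::abort("crop_max_frac must lie in [0, 0.5)", class = "ramangrade_validation")
  }
  structure(list(crop_max_frac = crop_max_frac, resize_to = as.integer(resize_to),
                 gauss_noise_sigma = gauss_noise_sigma,
                 sharpness_range = sharpness_range),
            class = "image_augment_config")
}

gaussian_blur3 <- function(img) {
  # separable 3x3 binomial blur with edge replication, per channel
  one <- function(m) {
    up <- m[c(1, seq_len(nrow(m) - 1L)), , drop = FALSE]
    dn <- m[c(seq_len(nrow(m))[-1], nrow(m)), , drop = FALSE]
    v <- (up + 2 * m + dn) / 4
    lf <- v[, c(1, seq_len(ncol(m) - 1L)), drop = FALSE]
    rt <- v[, c(seq_len(ncol(m))[-1], ncol(m)), drop = FALSE]
    (lf + 2 * v + rt) / 4
  }
  if (length(dim(img)) == 3L) {
    out <- img
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- one(img[, , ch])
    out
  } else one(img)
}

#' Augment one RGB image
#'
#' @param img 224x224x3 array.
#' @param cfg An [image_augment_config()].
#' @param seed Optional seed for the random draws.
#' @return Augmented image (z-scored pixel values, so no longer in `[0,1]`).
#' @export
augment_image <- function(img, cfg = image_augment_config(), seed = NULL) {
  with_opt_seed(seed, {
    d <- dim(img)
    max_off <- floor(cfg$crop_max_frac * d[1:2])
    oy <- if (max_off[1] > 0) sample.int(max_off[1] + 1L, 1L) - 1L else 0L
    ox <- if (max_off[2] > 0) sample.int(max_off[2] + 1L, 1L) - 1L else 0L
    out <- img[(1L + oy):d[1], (1L + ox):d[2], , drop = FALSE]
    if (oy > 0L || ox > 0L || d[1] != cfg$resize_to) {
      out <- resize_bilinear(out, cfg$resize_to, cfg$resize_to)
    }
    f <- stats::runif(1, cfg$sharpness_range[1], cfg$sharpness_range[2])
    if (f != 1) {
      bl <- gaussian_blur3(out)
      out <- bl + f * (out - bl)
    }
    mu <- mean(out); sdv <- stats::sd(as.vector(out))
    out <- if (sdv > 0) (out - mu) / sdv else out - mu
    if (cfg$gauss_noise_sigma > 0) {
      out <- out + array(stats::rnorm(length(out), 0, cfg$gauss_noise_sigma),
                         dim(out))
    }
    out
  })
}

normalize_image <- function(img) {
  mu <- mean(img); sdv <- stats::sd(as.vector(img))
  if (sdv > 0) (img - mu) / sdv else img - mu
}

stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

#' Train the stage-2 image classifier
#'
#' Cross-entropy on the softmax head (for two classes this is the binary
#' cross entropy of the softmax probability), Adam, class-balanced
#' weighted random sampling, and the 2D augmentations applied on the fly.
#'
#' @param model A [build_transfer_model()] model.
#' @param images List of 224x224x3 arrays.
#' @param labels Factor or character labels, one per image.
#' @param cfg A [train_config_2d()].
#' @param sampler_weights Optional per-image sampling weights.
#' @return The fitted model with `$history` and `$class_levels`.
#' @export
train_2d <- function(model, images, labels, cfg = train_config_2d(),
                     sampler_weights = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) {
    rlang::abort("training set must contain at least two classes",
                 class = "ramangrade_validation")
  }
  if (length(lev) != model$n_classes) {
    rlang::abort(sprintf("model head has %d classes but labels carry %d",
                         model$n_classes, length(lev)),
                 class = "ramangrade_validation")
  }
  y <- match(labels, lev)
  if (is.null(sampler_weights)) sampler_weights <- weighted_sampler_weights(labels)
  n <- length(images)
  with_opt_seed(cfg$seed, {
    history <- numeric(cfg$epochs)
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      order_idx <- sample.int(n, n, replace = TRUE, prob = sampler_weights)
      losses <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- order_idx[start:min(start + cfg$batch_size - 1L, n)]
        batch <- lapply(images[idx], function(im) {
          if (is.null(cfg$augment)) normalize_image(im)
          else augment_image(im, cfg$augment)
        })
        x <- stack_images(batch)
        z <- nn_forward(model$net, x, training = TRUE)
        lo <- loss_ce_logits(z, y[idx])
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
    model$class_levels <- lev
    model$history <- tibble::tibble(epoch = seq_len(cfg$epochs), loss = history)
    model
  })
}

#' Predict with the stage-2 classifier
#'
#' Images are z-scored per image (the eval-time counterpart of the
#' training normalization), passed through the network in eval mode and
#' softmaxed. Ties in the logits resolve to the lowest class index.
#'
#' @param model A trained [build_transfer_model()] model.
#' @param images List of 224x224x3 arrays.
#' @return Tibble with `label` and one `p_<class>` probability column per
#'   class (rows sum to 1).
#' @export
predict_2d <- function(model, images) {
  d <- dim(images[[1]])
  if (length(d) != 3L || d[3] != 3L) {
    rlang::abort("images must be height x width x 3 arrays",
                 class = "ramangrade_validation")
  }
  x <- stack_images(lapply(images, normalize_image))
  z <- nn_forward(model$net, x, training = FALSE)
  zmax <- apply(z, 1, max)
  P <- exp(z - zmax)
  P <- P / rowSums(P)
  lev <- model$class_levels %||% paste0("class", seq_len(model$n_classes))
  lab <- lev[apply(z, 1, which.max)]   # which.max: first (lowest) index on ties
  out <- tibble::tibble(label = lab)
  for (j in seq_along(lev)) out[[paste0("p_", lev[j])]] <- P[, j]
  out
}

#' @exportS3Method generics::tidy
tidy.cnn2d <- function(x, ...) {
  if (is.null(x$history)) tibble::tibble(epoch = integer(), loss = numeric())
  else x$history
}

#' @exportS3Method generics::glance
glance.cnn2d <- function(x, ...) {
  tibble::tibble(
    backbone = x$backbone,
    n_parameters = n_params(x$net),
    base_width = x$base_width,
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history) || nrow(x$history) == 0) NA_real_
                 else x$history$loss[nrow(x$history)]
  )
}
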