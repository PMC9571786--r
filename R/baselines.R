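#' PCA reduction fitted on training data only
#'
#' @param train_X,test_X Numeric matrices (samples x features).
#' @param k Number of principal components (default 30).
#' @return List with `train`, `test` (projected matrices) and
#'   `explained_variance_ratio` (non-increasing, sums to <= 1).
#' @export
pca_fit_transform <- function(train_X, test_X, k = 30L) {
  k <- as.integer(k)
  if (k > min(dim(train_X))) {
    rlang::abort(sprintf("k = %d exceeds min(n_train, n_features) = %d",
                         k, min(dim(train_X))),
                 class = "ramangrade_validation")
  }
  fit <- stats::prcomp(train_X, center = TRUE, scale. = FALSE, rank. = k)
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  list(train = fit$x[, seq_len(k), drop = FALSE],
       test = stats::predict(fit, test_X)[, seq_len(k), drop = FALSE],
       explained_variance_ratio = evr[seq_len(k)])
}

# internal matrix-input trainer shared by the ANN and CNN baselines
train_net_matrix <- function(net, X, y_int, n_classes, epochs, batch_size,
                             lr, weight_decay, conv_input = FALSE) {
  n <- nrow(X)
  w <- weighted_sampler_weights(y_int)
  step <- 0L
  for (ep in seq_len(epochs)) {
    order_idx <- sample.int(n, n, replace = TRUE, prob = w)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- order_idx[start:min(start + batch_size - 1L, n)]
      xb <- X[idx, , drop = FALSE]
      if (conv_input) xb <- array(xb, c(length(idx), ncol(X), 1L))
      z <- nn_forward(net, xb, training = TRUE)
      lo <- loss_ce_logits(z, y_int[idx])
      nn_backward(net, lo$grad)
      step <- step + 1L
      adam_step(net, step, lr, weight_decay = weight_decay)
    }
  }
  nn_clear_cache(net)
  net
}

predict_net_matrix <- function(net, X, conv_input = FALSE) {
  xb <- if (conv_input) array(X, c(nrow(X), ncol(X), 1L)) else X
  z <- nn_forward(net, xb, training = FALSE)
  apply(z, 1, which.max)
}

#' Fit a shallow baseline and predict test labels
#'
#' The comparison methods: `"pca_svm"` (30-component PCA then an RBF SVM
#' with `C = 1` and the scale heuristic `gamma = 1/(n_features *
#' Var(X))`, one-vs-one for more than two classes), `"pca_lda"` and
#' `"lda"` (SVD solver, rank tolerance 1e-4, no shrinkage), `"ann"` (a
#' multilayer perceptron with hidden layers 256 and 64, trained with the
#' same Adam settings as the cascade), and `"cnn1d"` (the stage-1
#' architecture with a multi-class head). If the training features are
#' all constant, every method degenerates to predicting the majority
#' class.
#'
#' @param method One of `"pca_svm"`, `"pca_lda"`, `"lda"`, `"ann"`,
#'   `"cnn1d"`.
#' @param train_X,test_X Feature matrices (samples x features).
#' @param train_y Training labels (>= 2 classes).
#' @param pca_components Components for the PCA variants (default 30).
#' @param epochs,batch_size,learning_rate,weight_decay Training loop
#'   settings for the neural baselines.
#' @param seed Integer seed; all methods reproduce exactly under it.
#' @return Character vector of predicted test labels.
#' @export
fit_predict_baseline <- function(method, train_X, train_y, test_X,
                                 pca_components = 30L, epochs = 60L,
                                 batch_size = 32L, learning_rate = 1e-3,
                                 weight_decay = 0.01, seed = 1L) {
  if (!method %in% c("pca_svm", "pca_lda", "lda", "ann", "cnn1d")) {
    rlang::abort(sprintf("unknown baseline method '%s'", method),
                 class = "ramangrade_validation")
  }
  train_y <- as.character(train_y)
  lev <- sort(unique(train_y))
  if (length(lev) < 2L) {
    rlang::abort("training labels must contain at least 2 classes",
                 class = "ramangrade_validation")
  }
  # degenerate rule: constant features carry no signal -> majority class
  if (all(apply(train_X, 2, function(v) max(v) - min(v)) == 0)) {
    maj <- names(sort(table(train_y), decreasing = TRUE))[1]
    return(rep(maj, nrow(test_X)))
  }
  with_opt_seed(seed, {
    if (method %in% c("pca_svm", "pca_lda")) {
      red <- pca_fit_transform(train_X, test_X, pca_components)
      train_X <- red$train; test_X <- red$test
    }
    switch(method,
      pca_svm = {
        gamma <- 1 / (ncol(train_X) * stats::var(as.vector(train_X)))
        fit <- e1071::svm(train_X, factor(train_y, levels = lev),
                          kernel = "radial", cost = 1, gamma = gamma,
                          scale = FALSE)
        as.character(stats::predict(fit, test_X))
      },
      pca_lda = ,
      lda = {
        fit <- MASS::lda(train_X, grouping = factor(train_y, levels = lev),
                         tol = 1e-4)
        as.character(stats::predict(fit, test_X)$class)
      },
      ann = {
        p <- ncol(train_X); K <- length(lev)
        net <- nn_network(list(
          layer_dense(p, 256L), layer_relu(),
          layer_dense(256L, 64L), layer_relu(),
          layer_dense(64L, K)))
        net <- train_net_matrix(net, train_X, match(train_y, lev), K,
                                epochs, batch_size, learning_rate, weight_decay)
        lev[predict_net_matrix(net, test_X)]
      },
      cnn1d = {
        K <- length(lev)
        model <- build_cnn1d(ncol(train_X), n_out = K,
                             seed = sample.int(.Machine$integer.max, 1))
        model$net <- train_net_matrix(model$net, train_X, match(train_y, lev),
                                      K, epochs, batch_size, learning_rate,
                                      weight_decay, conv_input = TRUE)
        lev[predict_net_matrix(model$net, test_X, conv_input = TRUE)]
      }
    )
  })
}

#' Fit a baseline as a drop-in cascade stage
#'
#' Pipeline mode for the shallow methods: the baseline is fitted on the
#' binary task's training spectra and returned as a predictor function
#' [run_cascade()] accepts in place of either network stage.
#'
#' @param method Baseline method as in [fit_predict_baseline()].
#' @param train A normalized `raman_spectra` training set.
#' @param task A [binary_task()].
#' @param ... Passed on to [fit_predict_baseline()].
#' @return A function mapping a `raman_spectra` set to per-spectrum
#'   labels: `"positive"`/`"negative"` for the stage-1 task, `"E"`/`"G1"`
#'   for the stage-2 task.
#' @export
fit_baseline_stage <- function(method, train, task, ...) {
  lab <- task_labels(task, train$meta$grade)
  keep <- !is.na(lab)
  train_X <- train$intensities[keep, , drop = FALSE]
  if (task$name == "E_vs_G1") {
    train_y <- collapse_grades(train$meta$grade)[keep]
  } else {
    train_y <- lab[keep]
  }
  args <- list(...)
  force(method)
  function(spectra) {
    do.call(fit_predict_baseline,
            c(list(method = method, train_X = train_X, train_y = train_y,
                   test_X = spectra$intensities), args))
  }
}

#' Run the baseline comparison in three-class mode
#'
#' Fits each requested method on the collapsed three-category task and
#' reports per-class and mean accuracy, one row per method.
#'
#' @param train,test Normalized `raman_spectra` sets.
#' @param methods Character vector of baseline methods.
#' @param ... Passed on to [fit_predict_baseline()].
#' @return Tibble with columns `method`, `acc_E`, `acc_G1`, `acc_G2G3`,
#'   `acc_mean` (count-weighted, %).
#' @export
baseline_comparison <- function(train, test,
                                methods = c("pca_svm", "pca_lda", "lda", "ann"),
                                ...) {
  train_y <- collapse_grades(train$meta$grade)
  test_y <- collapse_grades(test$meta$grade)
  purrr::map_dfr(methods, function(m) {
    pred <- fit_predict_baseline(m, train$intensities, train_y,
                                 test$intensities, ...)
    acc <- per_class_accuracy(pred, test_y, c("E", "G1", "G2G3"))
    tibble::tibble(method = m, acc_E = acc[["E"]], acc_G1 = acc[["G1"]],
                   acc_G2G3 = acc[["G2G3"]],
                   acc_mean = 100 * mean(pred == test_y))
  })
}
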