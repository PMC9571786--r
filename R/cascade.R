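#' Inverse-class-frequency sampling weights
#'
#' Weights proportional to `1 / count(class of i)`, normalized to sum to
#' one, so a weighted random sampler draws every class with equal
#' probability regardless of imbalance.
#'
#' @param labels Vector of class labels (anything coercible to character).
#' @return Numeric weights, one per element, summing to 1.
#' @export
weighted_sampler_weights <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    rlang::abort("labels must be non-empty", class = "ramangrade_validation")
  }
  counts <- table(labels)
  w <- 1 / as.numeric(counts[labels])
  w / sum(w)
}

#' Per-class accuracy in percent
#'
#' @param pred,true Equal-length label vectors.
#' @param classes Classes to report; each must occur in `true`.
#' @return Named numeric vector, `100 * correct_c / n_c` per class.
#' @export
per_class_accuracy <- function(pred, true, classes = sort(unique(true))) {
  pred <- as.character(pred); true <- as.character(true)
  if (length(pred) != length(true)) {
    rlang::abort("pred and true must have the same length",
                 class = "ramangrade_validation")
  }
  missing_cls <- setdiff(classes, unique(true))
  if (length(missing_cls)) {
    rlang::abort(sprintf("class absent from true labels: %s",
                         paste(missing_cls, collapse = ", ")),
                 class = "ramangrade_validation")
  }
  vapply(classes, function(cl) {
    idx <- true == cl
    100 * sum(pred[idx] == cl) / sum(idx)
  }, numeric(1))
}

#' Aggregate stage accuracies into the cascade's final accuracy report
#'
#' Combines the per-class accuracies of the two binary stages into final
#' per-class and mean three-class accuracies. High-grade samples
#' terminate at stage 1, so the final G2G3 accuracy is the stage-1 G2G3
#' accuracy; E and G1 samples must survive stage-1 routing *and* be
#' classified correctly at stage 2, so their final accuracies are the
#' products of the stage-2 per-class accuracy with the stage-1 EG1
#' accuracy. The final mean is the class-count-weighted mean of the three
#' final per-class accuracies.
#'
#' In `"fraction_counts"` mode (default) the percentage inputs are first
#' converted back to nearest-integer correct counts over their class
#' sizes, and the products are taken on the underlying fractions — the
#' arithmetic that printed accuracy tables imply (e.g. 83.3% of 24 is the
#' fraction 20/24, not 0.833). `"printed_products"` multiplies the
#' rounded percentages directly, for sensitivity checks.
#'
#' @param acc_EG1_stage1,acc_G2G3_stage1 Stage-1 per-class accuracies (%).
#' @param acc_E_stage2,acc_G1_stage2 Stage-2 per-class accuracies (%).
#' @param n_E,n_G1,n_G2G3 Test-set class counts.
#' @param rounding `"fraction_counts"` or `"printed_products"`.
#' @return A `cascade_report` object carrying the stage inputs, class
#'   counts, final per-class accuracies and the final mean accuracy, all
#'   in percent.
#' @export
aggregate_final_accuracy <- function(acc_EG1_stage1, acc_G2G3_stage1,
                                     acc_E_stage2, acc_G1_stage2,
                                     n_E, n_G1, n_G2G3,
                                     rounding = c("fraction_counts", "printed_products")) {
  rounding <- match.arg(rounding)
  accs <- c(acc_EG1_stage1, acc_G2G3_stage1, acc_E_stage2, acc_G1_stage2)
  if (any(accs < 0 | accs > 100)) {
    rlang::abort("accuracies must lie in [0, 100]", class = "ramangrade_validation")
  }
  if (any(c(n_E, n_G1, n_G2G3) <= 0)) {
    rlang::abort("class counts must be positive", class = "ramangrade_validation")
  }
  if (rounding == "fraction_counts") {
    n_EG1 <- n_E + n_G1
    f_EG1_1 <- round(acc_EG1_stage1 / 100 * n_EG1) / n_EG1
    f_G2G3_1 <- round(acc_G2G3_stage1 / 100 * n_G2G3) / n_G2G3
    f_E_2 <- round(acc_E_stage2 / 100 * n_E) / n_E
    f_G1_2 <- round(acc_G1_stage2 / 100 * n_G1) / n_G1
  } else {
    f_EG1_1 <- acc_EG1_stage1 / 100
    f_G2G3_1 <- acc_G2G3_stage1 / 100
    f_E_2 <- acc_E_stage2 / 100
    f_G1_2 <- acc_G1_stage2 / 100
  }
  acc_E_final <- 100 * f_E_2 * f_EG1_1
  acc_G1_final <- 100 * f_G1_2 * f_EG1_1
  acc_G2G3_final <- 100 * f_G2G3_1
  acc_final <- (n_E * acc_E_final + n_G1 * acc_G1_final +
                  n_G2G3 * acc_G2G3_final) / (n_E + n_G1 + n_G2G3)
  out <- structure(list(
    acc_EG1_stage1 = 100 * f_EG1_1, acc_G2G3_stage1 = 100 * f_G2G3_1,
    acc_E_stage2 = 100 * f_E_2, acc_G1_stage2 = 100 * f_G1_2,
    acc_E_final = acc_E_final, acc_G1_final = acc_G1_final,
    acc_G2G3_final = acc_G2G3_final,
    n_E = n_E, n_G1 = n_G1, n_G2G3 = n_G2G3,
    acc_final = acc_final, rounding = rounding
  ), class = "cascade_report")
  # the aggregation identities must hold in every report
  stopifnot(
    isTRUE(all.equal(out$acc_G2G3_final, out$acc_G2G3_stage1)),
    isTRUE(all.equal(out$acc_E_final,
                     out$acc_E_stage2 * out$acc_EG1_stage1 / 100)),
    isTRUE(all.equal(out$acc_G1_final,
                     out$acc_G1_stage2 * out$acc_EG1_stage1 / 100))
  )
  out
}

#' @export
print.cascade_report <- function(x, digits = 1, ...) {
  cat("Cascade accuracy report (", x$rounding, ")\n", sep = "")
  cat(sprintf("  stage 1: EG1 %.*f%%  G2G3 %.*f%%\n",
              digits, x$acc_EG1_stage1, digits, x$acc_G2G3_stage1))
  cat(sprintf("  stage 2: E %.*f%%  G1 %.*f%%\n",
              digits, x$acc_E_stage2, digits, x$acc_G1_stage2))
  cat(sprintf("  final  : E %.*f%%  G1 %.*f%%  G2G3 %.*f%%  (n = %d/%d/%d)\n",
              digits, x$acc_E_final, digits, x$acc_G1_final,
              digits, x$acc_G2G3_final, x$n_E, x$n_G1, x$n_G2G3))
  cat(sprintf("  mean   : %.*f%%\n", digits, x$acc_final))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cascade_report <- function(x, ...) {
  tibble::tibble(
    quantity = c("acc_EG1_stage1", "acc_G2G3_stage1", "acc_E_stage2",
                 "acc_G1_stage2", "acc_E_final", "acc_G1_final",
                 "acc_G2G3_final", "acc_final"),
    class = c("EG1", "G2G3", "E", "G1", "E", "G1", "G2G3", "all"),
    stage = c("stage1", "stage1", "stage2", "stage2",
              "final", "final", "final", "final"),
    accuracy = c(x$acc_EG1_stage1, x$acc_G2G3_stage1, x$acc_E_stage2,
                 x$acc_G1_stage2, x$acc_E_final, x$acc_G1_final,
                 x$acc_G2G3_final, x$acc_final)
  )
}

#' @exportS3Method generics::glance
glance.cascade_report <- function(x, ...) {
  tibble::tibble(acc_final = x$acc_final, acc_E_final = x$acc_E_final,
                 acc_G1_final = x$acc_G1_final,
                 acc_G2G3_final = x$acc_G2G3_final,
                 n = x$n_E + x$n_G1 + x$n_G2G3, rounding = x$rounding)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cascade_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$stage == "final" & df$class != "all", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$acc_final, linetype = 2) +
    ggplot2::labs(x = NULL, y = "final per-class accuracy (%)",
                  subtitle = sprintf("mean %.1f%%", object$acc_final)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

stage1_predict <- function(stage1, spectra, threshold = 0.5) {
  if (inherits(stage1, "cnn1d")) {
    if (!isTRUE(stage1$trained)) {
      rlang::abort("stage-1 model is untrained", class = "ramangrade_validation")
    }
    predict_1d(stage1, spectra, threshold)$label
  } else if (is.function(stage1)) {
    stage1(spectra)
  } else {
    rlang::abort("stage1 must be a cnn1d model or a predictor function",
                 class = "ramangrade_validation")
  }
}

stage2_predict <- function(stage2, spectra, wparams, ssq, out_size) {
  if (inherits(stage2, "cnn2d")) {
    if (!isTRUE(stage2$trained)) {
      rlang::abort("stage-2 model is untrained", class = "ramangrade_validation")
    }
    imgs <- spectra_to_images(spectra, wparams, ssq = ssq, out_size = out_size)
    predict_2d(stage2, imgs)$label
  } else if (is.function(stage2)) {
    stage2(spectra)
  } else {
    rlang::abort("stage2 must be a cnn2d model or a predictor function",
                 class = "ramangrade_validation")
  }
}

#' Run the full two-stage cascade on a test set
#'
#' Stage 1 labels every spectrum EG1 or G2G3; G2G3 calls terminate,
#' EG1-routed spectra are rendered to synchrosqueezed-CWT RGB images and
#' passed to stage 2, which assigns E or G1. Both stages may be the
#' package's fitted networks or arbitrary predictor functions (the route
#' baseline methods take in pipeline mode): stage 1 functions must return
#' `"positive"`/`"negative"` per spectrum, stage 2 functions `"E"`/`"G1"`.
#'
#' @param test A normalized `raman_spectra` set.
#' @param stage1 Trained [build_cnn1d()] model or predictor function.
#' @param stage2 Trained [build_transfer_model()] model or predictor
#'   function.
#' @param wparams [wavelet_params()] for the 1D-to-2D conversion.
#' @param ssq Synchrosqueeze before rendering (default TRUE).
#' @param out_size Image side length for stage 2.
#' @param threshold Stage-1 decision threshold.
#' @return Tibble with `spectrum_id`, `patient_id`, `true` (collapsed
#'   three-category grade), `stage1` routing and final `pred`.
#' @export
run_cascade <- function(test, stage1, stage2, wparams = wavelet_params(),
                        ssq = TRUE, out_size = 224L, threshold = 0.5) {
  s1 <- stage1_predict(stage1, test, threshold)
  pred <- rep("G2G3", length(s1))
  routed <- s1 == "positive"
  if (any(routed)) {
    pred[routed] <- stage2_predict(stage2, test[routed], wparams, ssq, out_size)
  }
  tibble::tibble(
    spectrum_id = test$meta$spectrum_id,
    patient_id = test$meta$patient_id,
    true = collapse_grades(test$meta$grade),
    stage1 = ifelse(routed, "EG1", "G2G3"),
    pred = pred
  )
}

#' Build a report from empirical cascade stage measurements
#'
#' Measures stage-1 per-class accuracy on the full test set and stage-2
#' per-class accuracy on the true-E/G1 samples stage 1 routed onward,
#' then recombines them with [aggregate_final_accuracy()].
#'
#' @param cascade_tbl Output of [run_cascade()].
#' @param rounding Passed to [aggregate_final_accuracy()];
#'   `"printed_products"` here because the inputs are exact empirical
#'   fractions, not printed table values.
#' @return A `cascade_report`.
#' @export
report_from_cascade <- function(cascade_tbl, rounding = "printed_products") {
  true <- cascade_tbl$true
  n_E <- sum(true == "E"); n_G1 <- sum(true == "G1"); n_G2G3 <- sum(true == "G2G3")
  s1_true <- ifelse(true %in% c("E", "G1"), "EG1", "G2G3")
  acc_EG1 <- 100 * sum(cascade_tbl$stage1 == "EG1" & s1_true == "EG1") /
    max(1L, sum(s1_true == "EG1"))
  acc_G2G3 <- 100 * sum(cascade_tbl$stage1 == "G2G3" & s1_true == "G2G3") /
    max(1L, sum(s1_true == "G2G3"))
  routed <- cascade_tbl$stage1 == "EG1"
  acc2 <- vapply(c("E", "G1"), function(cl) {
    idx <- routed & true == cl
    if (!any(idx)) return(0)
    100 * sum(cascade_tbl$pred[idx] == cl) / sum(idx)
  }, numeric(1))
  aggregate_final_accuracy(acc_EG1, acc_G2G3, acc2[["E"]], acc2[["G1"]],
                           n_E, n_G1, n_G2G3, rounding = rounding)
}
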