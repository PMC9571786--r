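#' Assemble a full-pipeline run configuration
#'
#' Bundles every knob of an end-to-end run: the synthetic cohort (or input
#' files), wavelet parameters, both training configurations and the output
#' directory. Each stochastic component receives a sub-seed derived from
#' `seed`, so one integer reproduces the whole run.
#'
#' @param seed Master integer seed.
#' @param cohort A [cohort_config()] (ignored when `input` is given).
#' @param input Optional list with `path`, `layout`, `meta` naming spectra
#'   files to load instead of simulating.
#' @param wavelet A [wavelet_params()].
#' @param ssq Synchrosqueeze before rendering stage-2 images.
#' @param image_size Side length of stage-2 images.
#' @param stage1 A [train_config_1d()].
#' @param stage2 A [train_config_2d()].
#' @param stage2_model List of [build_transfer_model()] arguments
#'   (`backbone`, `base_width`, `dropout_p`).
#' @param baselines Character vector of baseline methods to run in
#'   three-class mode (empty to skip).
#' @param out_dir Output directory for artifacts, or `NULL` to keep the
#'   run in memory.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_config(),
                       input = NULL,
                       wavelet = wavelet_params(nv = 16L),
                       ssq = TRUE,
                       image_size = 224L,
                       stage1 = train_config_1d(epochs = 40L),
                       stage2 = train_config_2d(epochs = 6L,
                                                learning_rate = 1e-3,
                                                batch_size = 16L),
                       stage2_model = list(backbone = "resnet18",
                                           base_width = 8L, dropout_p = 0.2),
                       baselines = character(),
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), cohort = cohort, input = input,
                 wavelet = wavelet, ssq = ssq,
                 image_size = as.integer(image_size),
                 stage1 = stage1, stage2 = stage2,
                 stage2_model = stage2_model, baselines = baselines,
                 out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Lossless round-trip: `read_run_config(write_run_config(cfg, path))`
#' reconstructs an identical configuration.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  ser <- unclass(config)
  ser$cohort <- unclass(ser$cohort)
  ser$cohort$bands <- lapply(seq_len(nrow(config$cohort$bands)), function(i) {
    as.list(config$cohort$bands[i, ])
  })
  ser$cohort$baseline_amp <- as.list(ser$cohort$baseline_amp)
  ser$cohort$train_counts <- as.list(ser$cohort$train_counts)
  ser$cohort$test_counts <- as.list(ser$cohort$test_counts)
  ser$cohort$patients_per_class <- as.list(ser$cohort$patients_per_class)
  ser$wavelet <- unclass(ser$wavelet)
  ser$stage1 <- unclass(ser$stage1)
  ser$stage2 <- unclass(ser$stage2)
  ser$stage2$augment <- if (is.null(config$stage2$augment)) NULL else
    unclass(config$stage2$augment)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  bands <- dplyr::bind_rows(lapply(y$cohort$bands, tibble::as_tibble))
  cohort <- cohort_config(
    grid = y$cohort$grid, bands = bands,
    band_contrast = y$cohort$band_contrast,
    baseline_amp = unlist(y$cohort$baseline_amp),
    baseline_shape = y$cohort$baseline_shape,
    rayleigh_amp = y$cohort$rayleigh_amp,
    rayleigh_decay = y$cohort$rayleigh_decay,
    patient_amp_sigma = y$cohort$patient_amp_sigma,
    patient_shift_sigma = y$cohort$patient_shift_sigma,
    spot_amp_sigma = y$cohort$spot_amp_sigma,
    spot_shift_sigma = y$cohort$spot_shift_sigma,
    tail_amp_sigma = y$cohort$tail_amp_sigma,
    noise_sigma = y$cohort$noise_sigma,
    train_counts = unlist(y$cohort$train_counts),
    test_counts = unlist(y$cohort$test_counts),
    patients_per_class = unlist(y$cohort$patients_per_class))
  wav <- wavelet_params(gamma = y$wavelet$gamma, beta = y$wavelet$beta,
                        nv = y$wavelet$nv,
                        scale_range = y$wavelet$scale_range)
  aug <- if (is.null(y$stage2$augment)) NULL else
    image_augment_config(crop_max_frac = y$stage2$augment$crop_max_frac,
                         resize_to = y$stage2$augment$resize_to,
                         gauss_noise_sigma = y$stage2$augment$gauss_noise_sigma,
                         sharpness_range = y$stage2$augment$sharpness_range)
  run_config(
    seed = y$seed, cohort = cohort, input = y$input, wavelet = wav,
    ssq = y$ssq, image_size = y$image_size,
    stage1 = do.call(train_config_1d, y$stage1),
    stage2 = do.call(train_config_2d,
                     c(y$stage2[setdiff(names(y$stage2), "augment")],
                       list(augment = aug))),
    stage2_model = y$stage2_model,
    baselines = unlist(y$baselines) %||% character(),
    out_dir = y$out_dir)
}

pipeline_log <- function(lines, out_dir) {
  message(paste(lines, collapse = "\n"))
  if (!is.null(out_dir)) {
    cat(lines, file = file.path(out_dir, "run.log"), sep = "\n", append = TRUE)
  }
}

#' Run the full cascade pipeline end to end
#'
#' Simulate (or load) a cohort, normalize, train stage 1 on EG1-vs-G2G3,
#' render synchrosqueezed scalogram images for the stage-2 training
#' classes, train stage 2 on E-vs-G1, run the cascade on the test split
#' and report per-class and aggregated accuracies; optionally run the
#' shallow baselines in three-class mode. When `config$out_dir` is set,
#' writes `report.json`, `predictions.csv`, `metrics.csv`, one sample
#' scalogram PNG per class and a `run.log` naming every derived seed.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list: `report` (a `cascade_report`),
#'   `cascade` (per-spectrum predictions), `stage1`, `stage2` (fitted
#'   models), `baselines` (tibble or NULL), `config`.
#' @export
run_full_pipeline <- function(config = run_config()) {
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  seeds <- list(cohort = config$seed, stage1 = config$seed + 1L,
                stage2 = config$seed + 2L)
  pipeline_log(c(sprintf("pipeline seed %d (cohort %d, stage1 %d, stage2 %d)",
                         config$seed, seeds$cohort, seeds$stage1, seeds$stage2)),
               out_dir)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "ramangrade_pipeline")
    })
  }

  cohort <- step("simulate/load", {
    if (!is.null(config$input)) {
      read_spectra_table(config$input$path, config$input$layout,
                         meta = config$input$meta)
    } else {
      generate_cohort(config$cohort, seed = seeds$cohort)
    }
  })
  splits <- step("split", cohort_split(cohort))
  train <- step("preprocess", normalize_spectra(splits$train))
  test <- step("preprocess", normalize_spectra(splits$test))
  pipeline_log(sprintf("cohort: %d train / %d test spectra",
                       length(train), length(test)), out_dir)

  task1 <- binary_task("EG1_vs_G2G3")
  cfg1 <- config$stage1
  cfg1$seed <- seeds$stage1
  stage1 <- step("train-1d", {
    m <- build_cnn1d(length(train$wavenumbers), seed = seeds$stage1)
    train_binary_1d(m, train, task1, cfg1)
  })

  eg1 <- collapse_grades(train$meta$grade) %in% c("E", "G1")
  imgs_train <- step("transform", {
    spectra_to_images(train[eg1], config$wavelet, ssq = config$ssq,
                      out_size = config$image_size)
  })
  cfg2 <- config$stage2
  cfg2$seed <- seeds$stage2
  stage2 <- step("train-2d", {
    m <- do.call(build_transfer_model,
                 c(config$stage2_model, list(n_classes = 2L, seed = seeds$stage2)))
    train_2d(m, imgs_train, collapse_grades(train$meta$grade)[eg1], cfg2)
  })

  cascade <- step("evaluate", {
    run_cascade(test, stage1, stage2, config$wavelet, ssq = config$ssq,
                out_size = config$image_size)
  })
  report <- step("evaluate", report_from_cascade(cascade))

  baselines <- NULL
  if (length(config$baselines)) {
    baselines <- step("baselines", {
      k <- min(30L, nrow(train$intensities) - 1L,
               ncol(train$intensities))
      if (k < 30L) {
        pipeline_log(sprintf("pca components capped at %d by cohort size", k),
                     out_dir)
      }
      baseline_comparison(train, test, methods = config$baselines,
                          pca_components = k, seed = config$seed)
    })
  }

  if (!is.null(out_dir)) {
    step("artifacts", {
      jsonlite::write_json(
        c(as.list(glance(report)),
          list(per_quantity = tidy(report),
               seeds = seeds)),
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
      readr::write_csv(cascade, file.path(out_dir, "predictions.csv"),
                       progress = FALSE)
      metrics <- dplyr::bind_rows(
        dplyr::mutate(tidy(stage1), stage = "stage1"),
        dplyr::mutate(tidy(stage2), stage = "stage2"))
      readr::write_csv(metrics, file.path(out_dir, "metrics.csv"),
                       progress = FALSE)
      if (!is.null(baselines)) {
        readr::write_csv(baselines, file.path(out_dir, "baselines.csv"),
                         progress = FALSE)
      }
      for (cl in c("E", "G1", "G2G3")) {
        i <- which(collapse_grades(test$meta$grade) == cl)[1]
        if (is.na(i)) next
        sc <- cwt(test$intensities[i, ], config$wavelet)
        if (config$ssq) sc <- synchrosqueeze(sc, test$intensities[i, ])
        write_rgb_png(scalogram_to_rgb(sc, config$image_size),
                      file.path(out_dir, sprintf("scalogram_%s.png", cl)))
      }
    })
    pipeline_log(sprintf("artifacts written to %s", out_dir), out_dir)
  }

  structure(list(report = report, cascade = cascade, stage1 = stage1,
                 stage2 = stage2, baselines = baselines, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  if (!is.null(x$baselines)) {
    cat("baselines (three-class):\n")
    print(as.data.frame(x$baselines), row.names = FALSE)
  }
  invisible(x)
}
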