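#' @importFrom rlang .data abort
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif sd approx
NULL

GRADE_LEVELS <- c("E", "G1", "G2", "G3", "G2G3", "unknown")

#' Default wavenumber grid
#'
#' The instrument range for the tissue study is 200--3400 cm^-1; the point
#' count is not dictated by the acquisition, so the package default is a
#' 1601-point grid (2 cm^-1 step, finer than the 5 cm^-1 FWHM spectral
#' resolution of the recordings it emulates).
#'
#' @param n Number of grid points.
#' @param range Two-element numeric, wavenumber range in cm^-1.
#' @return Strictly increasing numeric vector of length `n`.
#' @export
#' @examples
#' g <- default_wavenumber_grid()
#' length(g)          # 1601
#' diff(g)[1]         # 2 cm^-1
default_wavenumber_grid <- function(n = 1601L, range = c(200, 3400)) {
  seq(range[1], range[2], length.out = n)
}

parse_grade <- function(x) {
  g <- toupper(trimws(as.character(x)))
  g[g %in% c("", "NA", "UNKNOWN")] <- "unknown"
  g[g == "G2G3"] <- "G2G3"
  bad <- !(g %in% GRADE_LEVELS)
  g[bad] <- "unknown"
  g
}

#' Construct a set of Raman spectra on a shared wavenumber grid
#'
#' The container used throughout the package: an `n x p` intensity matrix,
#' a shared strictly increasing wavenumber grid (cm^-1) and a metadata
#' tibble with one row per spectrum (`spectrum_id`, `patient_id`, `grade`,
#' optionally `split`).
#'
#' @param wavenumbers Strictly increasing numeric grid in cm^-1.
#' @param intensities Numeric matrix, one spectrum per row, `ncol ==
#'   length(wavenumbers)`; a single spectrum may be given as a vector.
#' @param meta Data frame with one row per spectrum. Missing `spectrum_id`,
#'   `patient_id` or `grade` columns are filled with defaults
#'   (`s1, s2, ...`, `"unknown"`).
#' @return An object of class `raman_spectra`.
#' @export
raman_spectra <- function(wavenumbers, intensities, meta = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(intensities))) {
    intensities <- matrix(as.numeric(intensities), nrow = 1L)
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  p <- length(wavenumbers)
  n <- nrow(intensities)
  if (p < 2L) {
    abort("wavenumber grid must have at least 2 points", class = "ramangrade_validation")
  }
  if (ncol(intensities) != p) {
    abort(sprintf("intensity matrix has %d columns but grid has %d points",
                  ncol(intensities), p), class = "ramangrade_validation")
  }
  if (any(diff(wavenumbers) <= 0)) {
    abort("wavenumbers must be strictly increasing", class = "ramangrade_validation")
  }
  if (n > 0L && any(!is.finite(intensities))) {
    abort("all intensities must be finite", class = "ramangrade_validation")
  }
  if (is.null(meta)) meta <- tibble(.rows = n)
  meta <- as_tibble(meta)
  if (nrow(meta) != n) {
    abort("metadata must have one row per spectrum", class = "ramangrade_validation")
  }
  if (!"spectrum_id" %in% names(meta)) meta$spectrum_id <- paste0("s", seq_len(n))
  if (!"patient_id" %in% names(meta)) meta$patient_id <- "unknown"
  if (!"grade" %in% names(meta)) meta$grade <- "unknown"
  meta$spectrum_id <- as.character(meta$spectrum_id)
  meta$patient_id <- as.character(meta$patient_id)
  meta$grade <- parse_grade(meta$grade)
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities, meta = meta),
    class = "raman_spectra"
  )
}

#' @export
print.raman_spectra <- function(x, ...) {
  cat(sprintf("<raman_spectra> %d spectra x %d points, %.0f-%.0f cm^-1\n",
              nrow(x$intensities), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  tab <- table(x$meta$grade)
  cat("grades:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.raman_spectra <- function(x) nrow(x$intensities)

#' Subset a spectra set by spectrum index
#' @param x A `raman_spectra` object.
#' @param i Integer or logical index over spectra.
#' @param ... Unused.
#' @export
`[.raman_spectra` <- function(x, i, ...) {
  raman_spectra(x$wavenumbers, x$intensities[i, , drop = FALSE],
                x$meta[i, , drop = FALSE])
}

#' Combine spectra sets sharing one grid
#' @param ... `raman_spectra` objects on identical grids.
#' @export
bind_spectra <- function(...) {
  xs <- list(...)
  grid <- xs[[1]]$wavenumbers
  for (x in xs) {
    if (!isTRUE(all.equal(x$wavenumbers, grid))) {
      abort("cannot bind spectra on different grids", class = "ramangrade_validation")
    }
  }
  raman_spectra(grid, do.call(rbind, lapply(xs, `[[`, "intensities")),
                dplyr::bind_rows(lapply(xs, `[[`, "meta")))
}

#' Convert a spectra set to a long tibble
#'
#' @param x A `raman_spectra` object.
#' @param ... Unused.
#' @return Tibble with columns `spectrum_id`, `patient_id`, `grade`,
#'   `wavenumber`, `intensity`.
#' @exportS3Method tibble::as_tibble
as_tibble.raman_spectra <- function(x, ...) {
  n <- nrow(x$intensities)
  p <- length(x$wavenumbers)
  out <- tibble(
    spectrum_id = rep(x$meta$spectrum_id, each = p),
    patient_id  = rep(x$meta$patient_id, each = p),
    grade       = rep(x$meta$grade, each = p),
    wavenumber  = rep(x$wavenumbers, times = n),
    intensity   = as.vector(t(x$intensities))
  )
  if ("split" %in% names(x$meta)) {
    out$split <- rep(x$meta$split, each = p)
  }
  out
}

# ---- file I/O ---------------------------------------------------------------

meta_cols_present <- function(df) intersect(c("spectrum_id", "patient_id", "grade", "split"), names(df))

#' Read a spectra table from CSV/TSV
#'
#' Three layouts are supported. `wide_rows`: one spectrum per row; the
#' wavenumbers are the numeric column names, metadata travels in
#' `spectrum_id` / `patient_id` / `grade` (and optional `split`) columns.
#' `wide_cols`: one spectrum per column; the first column holds the
#' wavenumbers, the remaining column names are spectrum ids, and patient and
#' grade come from `meta`. `long`: columns `spectrum_id`, `wavenumber`,
#' `intensity` plus optional metadata columns.
#'
#' @param path File to read. Delimiter is inferred from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @param layout One of `"wide_rows"`, `"wide_cols"`, `"long"`.
#' @param meta Optional sidecar metadata: a data frame or a CSV path with
#'   columns `spectrum_id`, `patient_id`, `grade`.
#' @return A [raman_spectra] set on a single strictly increasing grid.
#' @export
read_spectra_table <- function(path, layout = c("wide_rows", "wide_cols", "long"),
                               meta = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ramangrade_io")
  }
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (is.character(meta)) {
    meta <- readr::read_csv(meta, show_col_types = FALSE, progress = FALSE)
  }
  out <- switch(layout,
    wide_rows = parse_wide_rows(df, path),
    wide_cols = parse_wide_cols(df, path),
    long      = parse_long(df, path)
  )
  if (!is.null(meta)) {
    meta <- as_tibble(meta)
    keep <- setdiff(names(out$meta), setdiff(names(meta), "spectrum_id"))
    out$meta <- dplyr::left_join(out$meta[, keep, drop = FALSE], meta,
                                 by = "spectrum_id")
    out <- raman_spectra(out$wavenumbers, out$intensities, out$meta)
  }
  out
}

# column-wise numeric coercion that keeps matrix shape for any row count
to_num_matrix <- function(df_part, path) {
  n <- nrow(df_part); p <- ncol(df_part)
  m <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    m[, j] <- suppressWarnings(as.numeric(df_part[[j]]))
  }
  if (n > 0L && any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric intensity in %s at row %d, column %d",
                  path, bad[1], bad[2]), class = "ramangrade_parse")
  }
  m
}

parse_wide_rows <- function(df, path) {
  meta_cols <- meta_cols_present(df)
  wn_cols <- setdiff(names(df), meta_cols)
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (any(is.na(wn))) {
    abort(sprintf("non-numeric wavenumber header in %s: %s", path,
                  paste(utils::head(wn_cols[is.na(wn)], 3), collapse = ", ")),
          class = "ramangrade_parse")
  }
  if (length(wn) >= 2 && any(diff(wn) <= 0)) {
    abort("wavenumber header is not strictly increasing",
          class = "ramangrade_validation")
  }
  ints <- to_num_matrix(df[, wn_cols, drop = FALSE], path)
  raman_spectra(wn, ints, df[, meta_cols, drop = FALSE])
}

parse_wide_cols <- function(df, path) {
  wn <- suppressWarnings(as.numeric(df[[1]]))
  if (any(is.na(wn))) {
    abort(sprintf("non-numeric wavenumber column in %s", path),
          class = "ramangrade_parse")
  }
  if (any(diff(wn) <= 0)) {
    abort("wavenumber column is not strictly increasing",
          class = "ramangrade_validation")
  }
  ids <- names(df)[-1]
  ints <- t(to_num_matrix(df[, -1, drop = FALSE], path))
  raman_spectra(wn, ints, tibble(spectrum_id = ids))
}

parse_long <- function(df, path) {
  need <- c("spectrum_id", "wavenumber", "intensity")
  if (!all(need %in% names(df))) {
    abort(sprintf("long layout needs columns %s", paste(need, collapse = ", ")),
          class = "ramangrade_parse")
  }
  df$intensity <- suppressWarnings(as.numeric(df$intensity))
  if (any(is.na(df$intensity))) {
    abort(sprintf("non-numeric intensity in %s at data row %d", path,
                  which(is.na(df$intensity))[1]), class = "ramangrade_parse")
  }
  ids <- unique(df$spectrum_id)
  wn <- sort(unique(df$wavenumber))
  wide <- tidyr::pivot_wider(df, id_cols = "spectrum_id",
                             names_from = "wavenumber",
                             values_from = "intensity")
  wide <- wide[match(ids, wide$spectrum_id), ]
  ord <- order(as.numeric(setdiff(names(wide), "spectrum_id")))
  ints <- as.matrix(wide[, setdiff(names(wide), "spectrum_id")[ord], drop = FALSE])
  meta_cols <- setdiff(meta_cols_present(df), "spectrum_id")
  meta <- dplyr::distinct(df[, c("spectrum_id", meta_cols), drop = FALSE])
  meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  raman_spectra(wn, ints, meta)
}

#' Write a spectra table to CSV/TSV
#'
#' Inverse of [read_spectra_table()]: files written here read back with
#' identical values and metadata.
#'
#' @param x A `raman_spectra` set.
#' @param path Output file; delimiter inferred from extension.
#' @param layout As in [read_spectra_table()]. `wide_cols` writes metadata
#'   to a `<path>.meta.csv` sidecar.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(x, path, layout = c("wide_rows", "wide_cols", "long")) {
  layout <- match.arg(layout)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- switch(layout,
    wide_rows = {
      ints <- as.data.frame(x$intensities)
      names(ints) <- as.character(x$wavenumbers)
      dplyr::bind_cols(x$meta, ints)
    },
    wide_cols = {
      m <- as.data.frame(t(x$intensities))
      names(m) <- x$meta$spectrum_id
      readr::write_csv(x$meta, paste0(path, ".meta.csv"), progress = FALSE)
      dplyr::bind_cols(tibble(wavenumber = x$wavenumbers), m)
    },
    long = as_tibble(x)
  )
  ok <- tryCatch({
    readr::write_delim(df, path, delim = delim, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
          class = "ramangrade_io")
  }
  invisible(path)
}

# ---- resampling -------------------------------------------------------------

#' Resample spectra onto a target wavenumber grid
#'
#' Linear interpolation; points outside the source range take the edge
#' value (constant extrapolation).
#'
#' @param x A `raman_spectra` set.
#' @param grid Strictly increasing target wavenumbers, overlapping the
#'   source range.
#' @return The set on the new grid.
#' @export
resample_to_grid <- function(x, grid) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) {
    abort("target grid must be strictly increasing", class = "ramangrade_validation")
  }
  rng <- range(x$wavenumbers)
  if (max(grid) < rng[1] || min(grid) > rng[2]) {
    abort("target grid does not overlap source range", class = "ramangrade_validation")
  }
  ints <- t(apply(x$intensities, 1, function(v) {
    approx(x$wavenumbers, v, xout = grid, rule = 2)$y
  }))
  if (nrow(x$intensities) == 1L) ints <- matrix(ints, nrow = 1L)
  raman_spectra(grid, ints, x$meta)
}

# ---- normalization and augmentation ----------------------------------------

#' Z-score normalize each spectrum
#'
#' Per-spectrum standardization to zero mean and unit *population*
#' standard deviation, the preprocessing both classifier stages expect.
#' Constant spectra cannot be standardized; they map to all zeros and are
#' flagged in a logical `degenerate` metadata column rather than erroring,
#' so batch pipelines do not abort.
#'
#' @param x A `raman_spectra` set.
#' @return The normalized set, with `meta$degenerate` added.
#' @export
normalize_spectra <- function(x) {
  p <- ncol(x$intensities)
  mu <- rowMeans(x$intensities)
  centered <- x$intensities - mu
  sd_pop <- sqrt(rowSums(centered^2) / p)
  degen <- sd_pop <= .Machine$double.eps * pmax(1, abs(mu)) * p
  scale_by <- ifelse(degen, 1, sd_pop)
  out <- centered / scale_by
  out[degen, ] <- 0
  meta <- x$meta
  meta$degenerate <- degen
  raman_spectra(x$wavenumbers, out, meta)
}

#' Additive Gaussian noise augmentation
#'
#' Adds zero-mean Gaussian noise to every spectrum. In
#' `"proportional_to_peak"` mode the standard deviation is
#' `relative_scale * max(intensities)` per spectrum, emulating detector
#' noise that scales with the strongest band; in `"absolute"` mode it is
#' `relative_scale` itself.
#'
#' @param x A `raman_spectra` set.
#' @param relative_scale Non-negative noise scale (default 0.05).
#' @param mode `"proportional_to_peak"` (default) or `"absolute"`.
#' @param seed Optional integer; when given, draws are made under this seed
#'   without disturbing the caller's RNG stream.
#' @return A new set; the input is unmodified.
#' @export
augment_noise <- function(x, relative_scale = 0.05,
                          mode = c("proportional_to_peak", "absolute"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (relative_scale < 0) {
    abort("relative_scale must be >= 0", class = "ramangrade_validation")
  }
  with_opt_seed(seed, {
    n <- nrow(x$intensities); p <- ncol(x$intensities)
    sigma <- if (mode == "proportional_to_peak") {
      relative_scale * apply(x$intensities, 1, max)
    } else {
      rep(relative_scale, n)
    }
    noise <- matrix(rnorm(n * p), n, p) * sigma
    raman_spectra(x$wavenumbers, x$intensities + noise, x$meta)
  })
}

#' Random integer spectral shift augmentation
#'
#' Shifts each spectrum by an integer number of grid steps drawn uniformly
#' from `[-s, s]`, emulating small wavelength-calibration offsets. Vacated
#' positions are filled with the edge value (constant extension), which on
#' z-scored spectra avoids fabricating band edges; the wavenumber grid is
#' unchanged. The default `s = 5` follows the regime where larger shifts
#' were found to hurt.
#'
#' @param x A `raman_spectra` set.
#' @param s Maximum shift in grid steps; non-negative integer smaller than
#'   the spectrum length.
#' @param seed Optional integer seed, as in [augment_noise()].
#' @return Shifted set.
#' @export
augment_shift <- function(x, s = 5L, seed = NULL) {
  s <- as.integer(s)
  if (s < 0L) abort("s must be >= 0", class = "ramangrade_validation")
  if (s >= ncol(x$intensities)) {
    abort("s must be smaller than the spectrum length", class = "ramangrade_validation")
  }
  with_opt_seed(seed, {
    k <- sample.int(2L * s + 1L, nrow(x$intensities), replace = TRUE) - s - 1L
    shift_spectra(x, k)
  })
}

#' Shift spectra by fixed step counts
#'
#' Deterministic companion to [augment_shift()]: shifts spectrum `i` by
#' `k[i]` grid steps (positive = toward higher wavenumbers), edge-padding
#' vacated positions.
#'
#' @param x A `raman_spectra` set.
#' @param k Integer vector (recycled) of shifts in grid steps.
#' @return Shifted set.
#' @export
shift_spectra <- function(x, k) {
  n <- nrow(x$intensities); p <- ncol(x$intensities)
  k <- rep_len(as.integer(k), n)
  out <- x$intensities
  for (i in seq_len(n)) {
    ki <- k[i]
    if (ki == 0L) next
    v <- x$intensities[i, ]
    idx <- seq_len(p) - ki
    idx[idx < 1L] <- 1L
    idx[idx > p] <- p
    out[i, ] <- v[idx]
  }
  raman_spectra(x$wavenumbers, out, x$meta)
}

with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- binary tasks -----------------------------------------------------------

#' Define one of the cascade's binary grading tasks
#'
#' The cascade always collapses G2 and G3 into one high-grade category.
#' `EG1_vs_G2G3` is the stage-1 task (benign+low-grade vs high-grade);
#' `E_vs_G1` is the stage-2 task on the samples stage 1 routes onward.
#' The first listed set is the positive class.
#'
#' @param name `"EG1_vs_G2G3"` or `"E_vs_G1"`.
#' @return A `binary_task` with `positive_classes` and `negative_classes`.
#' @export
binary_task <- function(name = c("EG1_vs_G2G3", "E_vs_G1")) {
  name <- match.arg(name)
  spec <- switch(name,
    EG1_vs_G2G3 = list(positive = c("E", "G1"), negative = c("G2", "G3", "G2G3")),
    E_vs_G1     = list(positive = "E", negative = "G1")
  )
  structure(list(name = name, positive_classes = spec$positive,
                 negative_classes = spec$negative),
            class = "binary_task")
}

#' Collapse raw grades onto the three cascade categories
#' @param grade Character vector of grades.
#' @return Character vector in `{E, G1, G2G3, unknown}`.
#' @export
collapse_grades <- function(grade) {
  g <- parse_grade(grade)
  g[g %in% c("G2", "G3")] <- "G2G3"
  g
}

task_labels <- function(task, grade) {
  g <- parse_grade(grade)
  lab <- rep(NA_character_, length(g))
  lab[g %in% task$positive_classes] <- "positive"
  lab[g %in% task$negative_classes] <- "negative"
  lab
}
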