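#' Default grade-dependent Raman band set
#'
#' The simulator's biochemical backbone, encoding the degradation gradients
#' reported for chondrogenic tissue: collagen bands (728, 830, 1206 cm^-1)
#' and chondroitin sulfate (1380 cm^-1) weaken progressively from
#' enchondroma (E) through G1 to high-grade G2G3; hydroxyapatite
#' (960 cm^-1) marks the calcified areas typical of G1 and peaks there;
#' nucleic-acid signal grows with malignant grade (cellular proliferation)
#' and is placed at the canonical DNA/RNA bands 785 and 1578 cm^-1 — a
#' simulator convention, since the tissue study reports the trend but not
#' the band positions it rode on. Two grade-neutral bands (amide I at
#' 1660 cm^-1 and the CH stretch near 2935 cm^-1) add realistic
#' non-discriminative structure.
#'
#' @return Tibble with one row per band: `band`, `center` (cm^-1), `width`
#'   (FWHM, cm^-1), `amplitude`, and grade multipliers `m_E`, `m_G1`,
#'   `m_G2G3`.
#' @export
default_band_set <- function() {
  tibble::tribble(
    ~band,          ~center, ~width, ~amplitude, ~m_E, ~m_G1, ~m_G2G3,
    "collagen_728",     728,     12,       0.90, 1.00,  0.78,    0.35,
    "collagen_830",     830,     12,       0.70, 1.00,  0.78,    0.35,
    "collagen_1206",   1206,     12,       0.60, 1.00,  0.78,    0.35,
    "chondroitin_1380",1380,     14,       0.80, 1.00,  0.75,    0.40,
    "hydroxyapatite_960",960,    10,       1.00, 0.25,  1.00,    0.15,
    "nucleic_785",      785,     12,       0.50, 0.30,  0.60,    1.00,
    "nucleic_1578",    1578,     14,       0.50, 0.30,  0.60,    1.00,
    "amide_I_1660",    1660,     22,       0.70, 1.00,  1.00,    1.00,
    "ch_stretch_2935", 2935,     60,       1.20, 1.00,  1.00,    1.00
  )
}

#' Configuration of the synthetic Raman cohort simulator
#'
#' Defaults reproduce the structure of the tissue study the package
#' emulates: 400 spectra from 10 patients (3/3/4 per class), class counts
#' 69/76/101 in training and 31/24/99 in test for (E, G1, G2G3), spectra on
#' the 1601-point 200--3400 cm^-1 grid, with a quadratic fluorescence
#' baseline, a decaying-exponential Rayleigh-scattering tail at the
#' low-wavenumber edge, patient-level amplitude and calibration effects,
#' and white detector noise.
#'
#' @param grid Shared wavenumber grid.
#' @param bands Band table as produced by [default_band_set()].
#' @param band_contrast Scale in `[0, 1]` applied to the grade dependence
#'   of every band multiplier and of the fluorescence amplitudes: 1 keeps
#'   the table as is, 0 removes all class differences (all grades share
#'   the across-grade means, so accuracy floors at the class prior).
#' @param baseline_amp Named per-grade fluorescence amplitudes.
#' @param baseline_shape Quadratic coefficients `(c0, c1, c2)` of the
#'   fluorescence shape over the normalized wavenumber axis.
#' @param rayleigh_amp,rayleigh_decay Amplitude and decay constant (cm^-1)
#'   of the Rayleigh tail `amp * exp(-(nu - nu_min)/decay)`.
#' @param patient_amp_sigma Log-scale SD of the per-patient multiplicative
#'   amplitude effect (log-normal).
#' @param patient_shift_sigma SD (cm^-1) of the per-patient wavenumber
#'   calibration offset.
#' @param spot_amp_sigma Log-scale SD of the per-spectrum (measurement
#'   spot) amplitude effect; Raman maps sample many regions per tissue
#'   section and spot-to-spot intensity varies substantially.
#' @param spot_shift_sigma SD (cm^-1) of the per-spectrum wavenumber
#'   jitter.
#' @param tail_amp_sigma Log-scale SD of the per-spectrum Rayleigh-tail
#'   amplitude (an instrument artifact, so it varies independently of the
#'   tissue signal).
#' @param noise_sigma Per-point Gaussian noise SD.
#' @param train_counts,test_counts Named integer class counts.
#' @param patients_per_class Named integers, each `>= 2` so a
#'   one-patient-per-class-out split exists.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(grid = default_wavenumber_grid(),
                          bands = default_band_set(),
                          band_contrast = 1,
                          baseline_amp = c(E = 0.5, G1 = 0.6, G2G3 = 0.8),
                          baseline_shape = c(1.0, -0.8, 0.25),
                          rayleigh_amp = 2.0,
                          rayleigh_decay = 100,
                          patient_amp_sigma = 0.15,
                          patient_shift_sigma = 1.5,
                          spot_amp_sigma = 0.10,
                          spot_shift_sigma = 0.5,
                          tail_amp_sigma = 0.2,
                          noise_sigma = 0.02,
                          train_counts = c(E = 69L, G1 = 76L, G2G3 = 101L),
                          test_counts = c(E = 31L, G1 = 24L, G2G3 = 99L),
                          patients_per_class = c(E = 3L, G1 = 3L, G2G3 = 4L)) {
  classes <- c("E", "G1", "G2G3")
  stopifnot(all(classes %in% names(train_counts)),
            all(classes %in% names(test_counts)),
            all(classes %in% names(patients_per_class)))
  if (any(patients_per_class[classes] < 2L)) {
    rlang::abort("patients_per_class must be >= 2 for every class",
                 class = "ramangrade_validation")
  }
  if (band_contrast < 0 || band_contrast > 1) {
    rlang::abort("band_contrast must lie in [0, 1]", class = "ramangrade_validation")
  }
  if (any(bands$width <= 0) || any(bands$amplitude < 0)) {
    rlang::abort("band widths must be positive and amplitudes non-negative",
                 class = "ramangrade_validation")
  }
  structure(list(
    grid = as.numeric(grid), bands = tibble::as_tibble(bands),
    band_contrast = band_contrast,
    baseline_amp = baseline_amp, baseline_shape = baseline_shape,
    rayleigh_amp = rayleigh_amp, rayleigh_decay = rayleigh_decay,
    patient_amp_sigma = patient_amp_sigma,
    patient_shift_sigma = patient_shift_sigma,
    spot_amp_sigma = spot_amp_sigma,
    spot_shift_sigma = spot_shift_sigma,
    tail_amp_sigma = tail_amp_sigma,
    noise_sigma = noise_sigma,
    train_counts = as.integer(train_counts[classes]) |> stats::setNames(classes),
    test_counts = as.integer(test_counts[classes]) |> stats::setNames(classes),
    patients_per_class = as.integer(patients_per_class[classes]) |> stats::setNames(classes)
  ), class = "cohort_config")
}

# multipliers after contrast scaling: shrink toward the across-grade mean
contrast_multipliers <- function(bands, contrast) {
  m <- as.matrix(bands[, c("m_E", "m_G1", "m_G2G3")])
  mbar <- rowMeans(m)
  mbar + contrast * (m - mbar)
}

#' Simulate one synthetic Raman spectrum
#'
#' Sum of Lorentzian bands (grade multipliers scaled by the cohort's
#' `band_contrast`, centers offset by the patient's calibration shift plus
#' a per-spectrum jitter, the whole profile scaled by the patient's and
#' the measurement spot's amplitude factors), plus the grade's
#' fluorescence baseline, the Rayleigh tail (its own per-spectrum
#' amplitude draw), and white noise.
#'
#' @param profile List with `patient_id`, `grade` (one of E/G1/G2G3),
#'   `amplitude_factor`, `wavenumber_offset`.
#' @param config A [cohort_config()].
#' @param seed Optional seed for the noise draw.
#' @return A single-spectrum [raman_spectra] set.
#' @export
synthesize_spectrum <- function(profile, config, seed = NULL) {
  grade <- parse_grade(profile$grade)
  if (!grade %in% c("E", "G1", "G2G3")) {
    rlang::abort(sprintf("cannot synthesize spectrum for grade '%s'", grade),
                 class = "ramangrade_validation")
  }
  with_opt_seed(seed, {
    nu <- config$grid
    mult <- contrast_multipliers(config$bands, config$band_contrast)
    mcol <- c(E = 1L, G1 = 2L, G2G3 = 3L)[[grade]]
    spot_amp <- exp(rnorm(1, 0, config$spot_amp_sigma))
    spot_shift <- rnorm(1, 0, config$spot_shift_sigma)
    tail_amp <- config$rayleigh_amp * exp(rnorm(1, 0, config$tail_amp_sigma))
    y <- numeric(length(nu))
    for (i in seq_len(nrow(config$bands))) {
      b <- config$bands[i, ]
      amp <- b$amplitude * mult[i, mcol]
      if (amp <= 0) next
      half <- b$width / 2
      center <- b$center + profile$wavenumber_offset + spot_shift
      y <- y + amp / (1 + ((nu - center) / half)^2)
    }
    y <- y * profile$amplitude_factor * spot_amp
    xn <- (nu - min(nu)) / (max(nu) - min(nu))
    bl_amp <- mean(config$baseline_amp) + config$band_contrast *
      (config$baseline_amp[[grade]] - mean(config$baseline_amp))
    bl <- bl_amp * profile$amplitude_factor * spot_amp *
      (config$baseline_shape[1] + config$baseline_shape[2] * xn +
         config$baseline_shape[3] * xn^2)
    tail <- tail_amp * exp(-(nu - min(nu)) / config$rayleigh_decay)
    y <- y + bl + tail
    if (config$noise_sigma > 0) {
      y <- y + rnorm(length(nu), 0, config$noise_sigma)
    }
    raman_spectra(nu, y, tibble(
      spectrum_id = paste0(profile$patient_id, "_x"),
      patient_id = profile$patient_id, grade = grade
    ))
  })
}

#' Generate a full synthetic cohort with patient-wise splits
#'
#' Creates `patients_per_class` patients per grade, reserves one patient
#' per class for the test split (the one-patient-per-class-out design) and
#' distributes the configured class counts round-robin over the patients
#' of each split, so patients never straddle splits. Patient amplitude
#' factors are log-normal and calibration offsets Gaussian, both drawn
#' once per patient.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; fixes patients, effects and noise.
#' @return A [raman_spectra] set with `meta` columns `spectrum_id`,
#'   `patient_id`, `grade`, `split` (`"train"`/`"test"`).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  with_opt_seed(seed, {
    classes <- c("E", "G1", "G2G3")
    sets <- list()
    for (cl in classes) {
      npat <- config$patients_per_class[[cl]]
      pids <- sprintf("P_%s_%d", cl, seq_len(npat))
      amp <- exp(rnorm(npat, 0, config$patient_amp_sigma))
      off <- rnorm(npat, 0, config$patient_shift_sigma)
      split_of <- c(rep("train", npat - 1L), "test")
      for (split in c("train", "test")) {
        pat_idx <- which(split_of == split)
        count <- if (split == "train") config$train_counts[[cl]] else config$test_counts[[cl]]
        owner <- pat_idx[(seq_len(count) - 1L) %% length(pat_idx) + 1L]
        for (j in seq_len(count)) {
          i <- owner[j]
          sp <- synthesize_spectrum(
            list(patient_id = pids[i], grade = cl,
                 amplitude_factor = amp[i], wavenumber_offset = off[i]),
            config)
          sp$meta$split <- split
          sets[[length(sets) + 1L]] <- sp
        }
      }
    }
    out <- do.call(bind_spectra, sets)
    out$meta$spectrum_id <- sprintf("%s_%04d", out$meta$patient_id,
                                    seq_len(nrow(out$meta)))
    out
  })
}

#' Split a cohort holding out one named patient per class
#'
#' @param x A `raman_spectra` set with `patient_id` and `grade` metadata.
#' @param held_out Named character vector or list mapping class to the
#'   patient id to hold out (e.g. `c(E = "P_E_3", ...)`).
#' @return List with `train` and `test` spectra sets; patient sets are
#'   disjoint and their union is the input.
#' @export
split_one_patient_per_class_out <- function(x, held_out) {
  held_out <- unlist(held_out)
  grades <- collapse_grades(x$meta$grade)
  for (cl in names(held_out)) {
    pid <- held_out[[cl]]
    hit <- x$meta$patient_id == pid
    if (!any(hit)) {
      rlang::abort(sprintf("patient '%s' not found", pid),
                   class = "ramangrade_validation")
    }
    if (!all(grades[hit] == cl)) {
      rlang::abort(sprintf("patient '%s' does not carry class '%s'", pid, cl),
                   class = "ramangrade_validation")
    }
    if (all(x$meta$patient_id[grades == cl] %in% held_out)) {
      rlang::abort(sprintf("holding out every patient of class '%s' leaves an empty training class", cl),
                   class = "ramangrade_validation")
    }
  }
  test_idx <- x$meta$patient_id %in% held_out
  list(train = x[!test_idx], test = x[test_idx])
}

#' Extract the train/test split tagged by the generator
#' @param x A cohort from [generate_cohort()].
#' @return List with `train` and `test` spectra sets.
#' @export
cohort_split <- function(x) {
  if (!"split" %in% names(x$meta)) {
    rlang::abort("cohort has no 'split' metadata column", class = "ramangrade_validation")
  }
  list(train = x[x$meta$split == "train"], test = x[x$meta$split == "test"])
}
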