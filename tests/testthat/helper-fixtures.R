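# Shared fixtures. Small cohorts keep unit tests fast; the desk-scale
# cascade protocol (helper-cascade.R) is reserved for the end-to-end
# accuracy checks.

# short grid for unit tests of spectra plumbing
tiny_grid <- function(n = 9L) seq(100, 500, length.out = n)

tiny_spectra <- function() {
  raman_spectra(
    tiny_grid(5L),
    rbind(c(1, 2, 3, 4, 5), c(2, 2, 2, 2, 2)),
    tibble::tibble(spectrum_id = c("a", "b"),
                   patient_id = c("p1", "p2"),
                   grade = c("E", "G1"))
  )
}

# reduced cohort: coarse grid, few spectra, 2 patients/class
small_cohort_config <- function(...) {
  cohort_config(
    grid = default_wavenumber_grid(401L),
    train_counts = c(E = 10L, G1 = 10L, G2G3 = 14L),
    test_counts = c(E = 4L, G1 = 4L, G2G3 = 6L),
    patients_per_class = c(E = 2L, G1 = 2L, G2G3 = 2L),
    ...
  )
}

# noiseless, effect-free config: spectra of one grade are identical
clean_cohort_config <- function(...) {
  args <- utils::modifyList(
    list(patient_amp_sigma = 0, patient_shift_sigma = 0,
         spot_amp_sigma = 0, spot_shift_sigma = 0,
         tail_amp_sigma = 0, noise_sigma = 0),
    list(...))
  do.call(small_cohort_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
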