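test_that("constructor enforces the container invariants", {
  expect_error(raman_spectra(c(500, 400, 600), matrix(1:3, 1)),
               class = "ramangrade_validation")
  expect_error(raman_spectra(1:3, matrix(c(1, NA, 3), 1)),
               class = "ramangrade_validation")
  expect_error(raman_spectra(1:3, matrix(1:4, 1)),
               class = "ramangrade_validation")
  x <- tiny_spectra()
  expect_s3_class(x, "raman_spectra")
  expect_equal(length(x), 2L)
  expect_equal(x$meta$grade, c("E", "G1"))
})

test_that("grades parse case-insensitively and unknowns are preserved", {
  x <- raman_spectra(1:3, matrix(1:3, 1), tibble::tibble(grade = "g1"))
  expect_equal(x$meta$grade, "G1")
  y <- raman_spectra(1:3, matrix(1:3, 1), tibble::tibble(grade = "whatever"))
  expect_equal(y$meta$grade, "unknown")
  expect_equal(collapse_grades(c("G2", "g3", "G2G3", "E")),
               c("G2G3", "G2G3", "G2G3", "E"))
})

test_that("spectra tables round-trip through every layout", {
  x <- tiny_spectra()
  for (layout in c("wide_rows", "wide_cols", "long")) {
    path <- file.path(tempfile(fileext = ".csv"))
    write_spectra_table(x, path, layout)
    meta <- if (layout == "wide_cols") paste0(path, ".meta.csv") else NULL
    y <- read_spectra_table(path, layout, meta = meta)
    expect_equal(y$wavenumbers, x$wavenumbers, tolerance = 1e-12)
    expect_equal(y$intensities, x$intensities, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(y$meta$grade, x$meta$grade)
    expect_equal(y$meta$patient_id, x$meta$patient_id)
  }
})

test_that("a 2-row wide file with 5 wavenumber columns parses directly", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("spectrum_id,patient_id,grade,100,200,300,400,500",
               "s1,p1,E,1,2,3,4,5",
               "s2,p1,E,5,4,3,2,1"), path)
  x <- read_spectra_table(path, "wide_rows")
  expect_equal(dim(x$intensities), c(2L, 5L))
})

test_that("non-monotone headers and non-numeric intensities are rejected", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("500,400,600", "1,2,3"), path)
  expect_error(read_spectra_table(path, "wide_rows"),
               class = "ramangrade_validation")
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("spectrum_id,100,200", "s1,1,oops"), path2)
  expect_error(read_spectra_table(path2, "wide_rows"),
               class = "ramangrade_parse")
})

test_that("empty and single-spectrum datasets survive a round trip", {
  empty <- raman_spectra(1:3, matrix(numeric(0), 0, 3))
  path <- tempfile(fileext = ".csv")
  write_spectra_table(empty, path, "wide_rows")
  back <- read_spectra_table(path, "wide_rows")
  expect_equal(length(back), 0L)
  one <- tiny_spectra()[1]
  path2 <- tempfile(fileext = ".csv")
  write_spectra_table(one, path2, "long")
  b2 <- read_spectra_table(path2, "long")
  expect_equal(b2$intensities, one$intensities, ignore_attr = TRUE)
  # long layout writes one data row per grid point
  expect_equal(nrow(readr::read_csv(path2, show_col_types = FALSE)), 5L)
})

test_that("resampling interpolates linearly and guards its inputs", {
  x <- raman_spectra(c(0, 1, 2, 3), matrix(c(0, 2, 4, 6), 1))
  same <- resample_to_grid(x, c(0, 1, 2, 3))
  expect_equal(same$intensities, x$intensities, ignore_attr = TRUE)
  mid <- resample_to_grid(x, c(0.5, 1.5, 2.5))
  expect_equal(as.vector(mid$intensities), c(1, 3, 5))
  # edge-value extrapolation outside the source range
  out <- resample_to_grid(x, c(-1, 0, 3, 4))
  expect_equal(as.vector(out$intensities), c(0, 0, 6, 6))
  expect_error(resample_to_grid(x, c(10, 20)), class = "ramangrade_validation")
  expect_error(resample_to_grid(x, c(1, 1, 2)), class = "ramangrade_validation")
  grid <- default_wavenumber_grid()
  expect_equal(length(grid), 1601L)
  expect_equal(diff(grid)[1], 2)
})

test_that("z-score normalization matches the population-sd definition", {
  n3 <- normalize_spectra(raman_spectra(1:3, matrix(c(1, 2, 3), 1)))
  expect_equal(as.vector(n3$intensities), c(-1.22474, 0, 1.22474),
               tolerance = 1e-5)
  const <- normalize_spectra(raman_spectra(1:3, matrix(c(5, 5, 5), 1)))
  expect_equal(as.vector(const$intensities), c(0, 0, 0))
  expect_true(const$meta$degenerate)
  set.seed(4)
  r <- normalize_spectra(raman_spectra(1:50, matrix(rnorm(50, 3, 7), 1)))
  expect_lt(abs(mean(r$intensities)), 1e-9)
  expect_lt(abs(sqrt(mean(r$intensities^2)) - 1), 1e-9)
  # idempotence on non-degenerate input
  again <- normalize_spectra(r)
  expect_equal(again$intensities, r$intensities, tolerance = 1e-9)
})

test_that("noise augmentation has the stated sigma and determinism", {
  x <- raman_spectra(1:20, matrix(seq(5, 100, length.out = 20), 1))
  expect_equal(augment_noise(x, 0)$intensities, x$intensities)
  expect_error(augment_noise(x, -1), class = "ramangrade_validation")
  # Monte-Carlo: peak 100, scale 0.05 -> sd 5 within 3%
  big <- raman_spectra(1:20, matrix(rep(seq(5, 100, length.out = 20), 500),
                                    500, 20, byrow = TRUE))
  out <- augment_noise(big, 0.05, seed = 9)
  resid <- out$intensities - big$intensities
  expect_equal(sd(as.vector(resid)), 5, tolerance = 0.03)
  # absolute mode
  out2 <- augment_noise(big, 0.7, mode = "absolute", seed = 9)
  expect_equal(sd(as.vector(out2$intensities - big$intensities)), 0.7,
               tolerance = 0.03)
  expect_equal(augment_noise(x, 0.1, seed = 5)$intensities,
               augment_noise(x, 0.1, seed = 5)$intensities)
})

test_that("spectral shifts move samples by whole grid steps with edge fill", {
  imp <- numeric(21); imp[11] <- 1
  x <- raman_spectra(1:21, matrix(imp, 1))
  expect_equal(augment_shift(x, 0)$intensities, x$intensities)
  sh <- shift_spectra(x, 2L)
  expect_equal(which(sh$intensities[1, ] == 1), 13L)
  expect_equal(sh$wavenumbers, x$wavenumbers)
  expect_error(augment_shift(x, 21L), class = "ramangrade_validation")
  # draws stay within [-s, s]
  ramp <- raman_spectra(1:50, matrix(rep(1:50, 40), 40, byrow = TRUE))
  shifted <- augment_shift(ramp, 5L, seed = 3)
  k_obs <- apply(shifted$intensities, 1, function(v) 26 - v[26])
  expect_true(all(abs(k_obs) <= 5))
  expect_equal(augment_shift(ramp, 5L, seed = 8)$intensities,
               augment_shift(ramp, 5L, seed = 8)$intensities)
})

test_that("a forced shift is undone by its inverse away from the edges", {
  set.seed(11)
  x <- raman_spectra(1:40, matrix(rnorm(40), 1))
  for (k in c(3L, -4L)) {
    back <- shift_spectra(shift_spectra(x, k), -k)
    core <- (2 * abs(k) + 1):(40 - 2 * abs(k))
    expect_equal(back$intensities[1, core], x$intensities[1, core])
  }
})

test_that("binary tasks collapse G2/G3 and label grades disjointly", {
  t1 <- binary_task("EG1_vs_G2G3")
  expect_setequal(t1$positive_classes, c("E", "G1"))
  expect_length(intersect(t1$positive_classes, t1$negative_classes), 0L)
  expect_true(all(c("G2", "G3", "G2G3") %in% t1$negative_classes))
  t2 <- binary_task("E_vs_G1")
  expect_equal(t2$positive_classes, "E")
})
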