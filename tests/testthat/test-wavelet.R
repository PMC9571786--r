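test_that("the Morse filter peaks at (beta/gamma)^(1/gamma) and is analytic", {
  p <- wavelet_params(gamma = 3, beta = 60, nv = 8)
  n <- 4096L
  resp <- gmw_frequency_response(1, n, p)
  omega <- 2 * pi * (0:(n - 1)) / n
  peak_omega <- omega[which.max(resp)]
  expect_equal(peak_omega, (60 / 3)^(1 / 3), tolerance = 1e-3)
  expect_equal(resp[1], 0)           # zero response at omega = 0
  # peak-normalized against the continuous maximum; the DFT grid need
  # not contain the exact peak frequency
  expect_equal(max(resp), 1, tolerance = 1e-4)
  # negative-frequency half of the DFT grid is zero
  expect_true(all(resp[(n / 2 + 2):n] == 0))
  # doubling the scale halves the peak frequency
  resp2 <- gmw_frequency_response(2, n, p)
  expect_equal(omega[which.max(resp2)], peak_omega / 2, tolerance = 1e-2)
  expect_error(gmw_frequency_response(-1, n, p), class = "ramangrade_validation")
  expect_error(wavelet_params(gamma = 0), class = "ramangrade_validation")
})

test_that("cwt is linear, rejects short input and zeroes on zero input", {
  p <- wavelet_params(nv = 8)
  expect_error(cwt(rnorm(5), p), class = "ramangrade_validation")
  expect_error(cwt(c(rnorm(10), Inf), p), class = "ramangrade_validation")
  expect_equal(max(Mod(cwt(rep(0, 32), p)$values)), 0)
  s <- rnorm(64)
  expect_equal(cwt(3.5 * s, p)$values, 3.5 * cwt(s, p)$values,
               tolerance = 1e-12)
})

test_that("fast cwt equals direct quadrature of the transform integral", {
  # oracle: sample the scaled wavelet in time via inverse DFT of its
  # frequency response, then evaluate the convolution sum directly
  p <- wavelet_params(nv = 8)
  set.seed(21)
  for (n in c(32L, 64L)) {
    s <- rnorm(n)
    sc <- cwt(s, p)
    M <- 2^ceiling(log2(2 * n))
    pad <- ramangrade:::pad_signal(s, M)
    scale_mag <- max(Mod(sc$values))
    for (j in sample(seq_along(sc$scales), 5)) {
      filt <- gmw_frequency_response(sc$scales[j], M, p)
      psi <- stats::fft(filt, inverse = TRUE) / M
      for (b in sample(seq_len(n), 2)) {
        tt <- seq_len(M)
        w_direct <- sum(pad$x * Conj(psi[((tt - (pad$left + b)) %% M) + 1]))
        expect_lt(Mod(w_direct - sc$values[j, b]) / scale_mag, 1e-6)
      }
    }
  }
})

test_that("a pure tone's ridge sits at the matching center frequency", {
  p <- wavelet_params(nv = 8)
  f0 <- 0.07
  s <- cos(2 * pi * f0 * (1:256))
  sc <- cwt(s, p)
  ridge <- which.max(rowMeans(Mod(sc$values)))
  # within one voice of the true frequency
  expect_lt(abs(log2(sc$freqs[ridge] / f0)), 1 / p$nv + 1e-9)
})

test_that("shifting the input shifts interior scalogram columns", {
  p <- wavelet_params(nv = 8)
  set.seed(3)
  bump <- exp(-((1:128) - 50)^2 / 18)
  k <- 9L
  bump_k <- c(rep(0, k), bump)[1:128]
  a <- cwt(bump, p); b <- cwt(bump_k, p)
  core <- 40:90
  # covariance holds away from the edge-affected rows: long-wavelet
  # (low-frequency) rows reach the reflection padding, and near-Nyquist
  # filters are frequency-truncated (long time tails), so compare the
  # mid-band rows
  live <- which(a$freqs >= 0.125 & a$freqs <= 0.40)
  expect_gt(length(live), 10L)
  expect_lt(max(Mod(b$values[live, core + k] - a$values[live, core])),
            1e-4 * max(Mod(a$values)))
})

test_that("synchrosqueezing conserves energy and sharpens tones", {
  p <- wavelet_params(nv = 8)
  f0 <- 0.06
  s <- cos(2 * pi * f0 * (1:256))
  sc <- cwt(s, p)
  ss <- synchrosqueeze(sc, s, p)
  expect_equal(sum(Mod(ss$values)^2), sum(Mod(sc$values)^2),
               tolerance = 0.01)
  bin <- which.min(abs(log(ss$freqs / f0)))
  near <- max(1, bin - 2):min(length(ss$freqs), bin + 2)
  expect_gt(sum(Mod(ss$values[near, ])^2) / sum(Mod(ss$values)^2), 0.9)
  # zero in, zero out
  z <- cwt(rep(0, 64), p)
  expect_equal(max(Mod(synchrosqueeze(z, rep(0, 64), p)$values)), 0)
  # magnitude-only input lacks the phase the transform needs
  mag_only <- sc; mag_only$values <- Mod(sc$values)
  expect_error(synchrosqueeze(mag_only, s, p), class = "ramangrade_validation")
})

test_that("two separated tones produce two disjoint ssq ridges", {
  p <- wavelet_params(nv = 8)
  s <- cos(2 * pi * 0.03 * (1:512)) + cos(2 * pi * 0.2 * (1:512))
  ss <- synchrosqueeze(cwt(s, p), s, p)
  row_energy <- rowSums(Mod(ss$values)^2)
  hot <- which(row_energy > 0.1 * max(row_energy))
  # hot rows split into exactly two contiguous groups
  expect_equal(sum(diff(hot) > 2), 1L)
  b1 <- which.min(abs(log(ss$freqs / 0.2)))
  b2 <- which.min(abs(log(ss$freqs / 0.03)))
  expect_true(any(abs(hot - b1) <= 2) && any(abs(hot - b2) <= 2))
})

test_that("the transform inverts within tolerance for band-limited signals", {
  p <- wavelet_params(nv = 16)
  # two-band spectrum built from Gabor atoms so the signal is
  # band-limited within the scale coverage (plain bumps carry energy
  # below the lowest analyzed frequency, which no wavelet sum recovers)
  t <- 1:512
  sig <- exp(-((t - 180)^2) / 400) * cos(2 * pi * 0.05 * t) +
    0.7 * exp(-((t - 330)^2) / 900) * cos(2 * pi * 0.12 * t)
  rec <- invert_cwt(cwt(sig, p), p)
  expect_lt(sqrt(sum((rec - sig)^2) / sum(sig^2)), 0.05)
  # zero round-trip
  expect_equal(max(abs(invert_cwt(cwt(rep(0, 64), p), p))), 0)
  # after synchrosqueezing a pure tone the waveform correlates >= 0.99
  tone <- cos(2 * pi * 0.08 * (1:256))
  ss <- synchrosqueeze(cwt(tone, p), tone, p)
  expect_gt(cor(invert_cwt(ss, p), tone), 0.99)
  # mismatched parameters are rejected
  expect_error(invert_cwt(cwt(sig, p), wavelet_params(nv = 8)),
               class = "ramangrade_validation")
})

test_that("jet colormap hits the classic anchor colors", {
  ends <- jet_colormap(c(0, 0.5, 1))
  expect_equal(ends[1, ], c(0, 0, 0.5), tolerance = 0.06)   # dark blue
  expect_equal(ends[3, ], c(0.5, 0, 0), tolerance = 0.06)   # dark red
  expect_gt(ends[2, 2], 0.9)                                # green middle
  expect_true(all(jet_colormap(seq(0, 1, 0.01)) >= 0 &
                    jet_colormap(seq(0, 1, 0.01)) <= 1))
})

test_that("scalogram rendering obeys shape, scale-invariance and degeneracy", {
  p <- wavelet_params(nv = 8)
  s <- rnorm(64)
  sc <- cwt(s, p)
  img <- scalogram_to_rgb(sc)
  expect_equal(dim(img), c(224L, 224L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  sc2 <- sc; sc2$values <- sc$values * 17
  expect_equal(scalogram_to_rgb(sc2), img, tolerance = 1e-12)
  # constant scalogram renders the value-0 color everywhere
  const <- sc; const$values <- sc$values * 0 + 3
  cimg <- scalogram_to_rgb(const)
  expect_equal(unique(as.vector(cimg[, , 1])), jet_colormap(0)[1])
  expect_equal(unique(as.vector(cimg[, , 3])), jet_colormap(0)[3])
  # the global maximum renders the endpoint color (dark red)
  fake <- sc
  fake$values <- matrix(0, 8, 8); fake$values[3, 5] <- 2
  fimg <- scalogram_to_rgb(fake, out_size = 8L)
  expect_equal(fimg[3, 5, ], jet_colormap(1)[1, ], ignore_attr = TRUE)
  nan_sc <- sc; nan_sc$values[] <- NA_real_
  expect_error(scalogram_to_rgb(nan_sc), class = "ramangrade_validation")
})

test_that("png round-trip preserves the rendered image", {
  p <- wavelet_params(nv = 8)
  img <- scalogram_to_rgb(cwt(rnorm(64), p), out_size = 32L)
  path <- tempfile(fileext = ".png")
  write_rgb_png(img, path)
  back <- png::readPNG(path)
  expect_equal(back, unclass(img), tolerance = 1 / 255)
})
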