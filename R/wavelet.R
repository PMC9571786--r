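#' Generalized Morse wavelet / CWT parameters
#'
#' The transform uses the analytic generalized Morse wavelet family with
#' shape parameters `gamma` (symmetry) and `beta` (time-bandwidth), log
#' spaced scales with `nv` voices per octave. Defaults follow the common
#' "gmw" convention (`gamma = 3`, `beta = 60`) with `nv = 64`; the scale
#' range is derived from the signal length when not given (dyadic
#' coverage from the Nyquist-peaked scale down to wavelets spanning about
#' a quarter of the signal).
#'
#' @param gamma,beta Positive Morse shape parameters.
#' @param nv Voices per octave (integer >= 1).
#' @param scale_range Optional `(a_min, a_max)`; `NULL` for automatic.
#' @return A `wavelet_params` object.
#' @export
wavelet_params <- function(gamma = 3, beta = 60, nv = 64L, scale_range = NULL) {
  if (gamma <= 0 || beta <= 0 || nv < 1) {
    rlang::abort("gamma > 0, beta > 0 and nv >= 1 required",
                 class = "ramangrade_validation")
  }
  structure(list(gamma = gamma, beta = beta, nv = as.integer(nv),
                 scale_range = scale_range, family = "gmw",
                 scale_spacing = "log"),
            class = "wavelet_params")
}

# peak angular frequency of the Morse filter omega^beta exp(-omega^gamma)
gmw_peak_omega <- function(params) (params$beta / params$gamma)^(1 / params$gamma)

# peak-normalized Morse magnitude response, evaluated in log space so
# beta = 60 does not overflow
gmw_eval <- function(omega, params) {
  wp <- gmw_peak_omega(params)
  out <- numeric(length(omega))
  pos <- omega > 0
  r <- omega[pos] / wp
  out[pos] <- exp(params$beta * log(r) +
                    (params$beta / params$gamma) * (1 - r^params$gamma))
  out
}

#' Sampled frequency response of a scaled generalized Morse wavelet
#'
#' Returns the analytic (one-sided) filter evaluated on the length-`n`
#' DFT angular-frequency grid `omega_k = 2*pi*k/n`, scaled by `scale`
#' and peak-normalized to 1. Only the non-negative frequency half is
#' non-zero; the response at `omega = 0` is exactly 0.
#'
#' @param scale Positive scale `a`.
#' @param n Grid length (>= 2).
#' @param params A [wavelet_params()].
#' @return Numeric vector of length `n`.
#' @export
gmw_frequency_response <- function(scale, n, params = wavelet_params()) {
  if (scale <= 0) {
    rlang::abort("scale must be positive", class = "ramangrade_validation")
  }
  n <- as.integer(n)
  if (n < 2L) rlang::abort("n must be >= 2", class = "ramangrade_validation")
  k <- 0:(n - 1L)
  omega <- 2 * pi * k / n
  # one-sided: zero out the negative-frequency half of the DFT grid
  omega[k > n %/% 2] <- -1
  gmw_eval(scale * pmax(omega, 0), params) * (omega > 0)
}

# log-spaced scale ladder; a_min peaks at Nyquist, a_max at ~4 samples/cycle
# of the full length
cwt_scales <- function(n, params) {
  wp <- gmw_peak_omega(params)
  if (!is.null(params$scale_range)) {
    a_min <- params$scale_range[1]; a_max <- params$scale_range[2]
  } else {
    a_min <- wp / pi
    a_max <- a_min * n / 4
  }
  J <- floor(params$nv * log2(a_max / a_min))
  a_min * 2^((0:J) / params$nv)
}

# triangular reflection fold of any integer position onto 1..n
fold_index <- function(t, n) {
  j <- (t - 1L) %% (2L * n - 2L)
  ifelse(j < n, j + 1L, 2L * n - 1L - j)
}

pad_signal <- function(s, M) {
  n <- length(s)
  left <- (M - n) %/% 2L
  t <- (1L - left):(M - left)
  list(x = s[fold_index(t, n)], left = left)
}

#' Continuous wavelet transform with a generalized Morse wavelet
#'
#' Computes the analytic CWT as per-scale frequency-domain products on a
#' reflection-padded copy of the signal, with `nv` log-spaced voices per
#' octave. Rows are scales (highest center frequency first is row 1's
#' smallest scale), columns align with the input samples.
#'
#' @param signal Finite numeric vector, length >= 8.
#' @param params A [wavelet_params()].
#' @return A `scalogram` object: complex `values` (scales x positions),
#'   `scales`, `freqs` (center frequencies, cycles/sample), `positions`,
#'   `kind = "cwt"` and the `params` used.
#' @export
cwt <- function(signal, params = wavelet_params()) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 8L) {
    rlang::abort("signal must have at least 8 samples", class = "ramangrade_validation")
  }
  if (any(!is.finite(signal))) {
    rlang::abort("signal must be finite", class = "ramangrade_validation")
  }
  M <- 2^ceiling(log2(2L * n))
  pad <- pad_signal(signal, M)
  fhat <- stats::fft(pad$x)
  scales <- cwt_scales(n, params)
  wp <- gmw_peak_omega(params)
  vals <- matrix(complex(real = 0), length(scales), n)
  sel <- (pad$left + 1L):(pad$left + n)
  for (j in seq_along(scales)) {
    filt <- gmw_frequency_response(scales[j], M, params)
    wj <- stats::fft(fhat * filt, inverse = TRUE) / M
    vals[j, ] <- wj[sel]
  }
  structure(list(values = vals, scales = scales,
                 freqs = wp / (2 * pi * scales),
                 positions = seq_len(n), kind = "cwt", params = params),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram:%s> %d scales x %d positions, freq %.4g-%.4g cycles/sample\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Synchrosqueeze a CWT scalogram
#'
#' Estimates the instantaneous frequency at every cell from the phase
#' derivative of the transform and reassigns each cell's energy to the
#' log-spaced frequency bin (one per CWT voice) nearest that estimate.
#' The output cell carries the square root of the accumulated
#' squared magnitude with the phase of the accumulated complex sum, so
#' total squared magnitude is conserved exactly in the mask-free case
#' while ridge phase is retained for reconstruction.
#'
#' @param scal Complex `scalogram` from [cwt()].
#' @param signal The signal the scalogram was computed from.
#' @param params The same [wavelet_params()] used for the forward transform.
#' @return A `scalogram` with `kind = "ssq"`; rows are frequency bins
#'   (the CWT center-frequency ladder), columns the input samples.
#' @export
synchrosqueeze <- function(scal, signal, params = scal$params) {
  if (!is.complex(scal$values)) {
    rlang::abort("synchrosqueezing needs the complex CWT (phase required)",
                 class = "ramangrade_validation")
  }
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n != ncol(scal$values)) {
    rlang::abort("signal length does not match scalogram positions",
                 class = "ramangrade_validation")
  }
  M <- 2^ceiling(log2(2L * n))
  pad <- pad_signal(signal, M)
  fhat <- stats::fft(pad$x)
  sel <- (pad$left + 1L):(pad$left + n)
  omega_grid <- 2 * pi * (0:(M - 1L)) / M
  omega_grid[(0:(M - 1L)) > M %/% 2] <- 0
  scales <- scal$scales
  freqs <- scal$freqs            # descending in scale index
  nb <- length(freqs)
  f_hi <- freqs[1]
  energy <- matrix(0, nb, n)
  csum <- matrix(complex(real = 0), nb, n)
  nvl <- params$nv
  for (j in seq_along(scales)) {
    filt <- gmw_frequency_response(scales[j], M, params)
    dW <- (stats::fft(fhat * (filt * omega_grid), inverse = TRUE) / M)[sel]
    W <- scal$values[j, ]
    mag2 <- Mod(W)^2
    live <- mag2 > 0
    if (!any(live)) next
    # d/db W = i * dW here, so the instantaneous frequency in
    # cycles/sample is Im(i*dW / W)/(2*pi) = Re(dW / W)/(2*pi)
    winst <- Re(dW[live] / W[live]) / (2 * pi)
    winst[!is.finite(winst) | winst <= 0] <- freqs[j]
    bins <- round(nvl * log2(f_hi / winst)) + 1L
    bins[bins < 1L] <- 1L
    bins[bins > nb] <- nb
    cols <- which(live)
    flat <- (cols - 1L) * nb + bins
    energy[flat] <- energy[flat] + mag2[live]
    csum[flat] <- csum[flat] + W[live]
  }
  phase <- ifelse(Mod(csum) > 0, Arg(csum), 0)
  vals <- complex(modulus = sqrt(energy), argument = phase)
  dim(vals) <- dim(energy)
  # the complex-sum accumulator is kept alongside: reassignment is
  # energy-conserving in `values`, while reconstruction needs the
  # amplitude-faithful complex sums
  structure(list(values = vals, scales = scales, freqs = freqs,
                 positions = scal$positions, kind = "ssq", params = params,
                 csum = csum),
            class = "scalogram")
}

# admissibility-type constant  C = int_0^inf g(omega) dln(omega), computed
# once per shape by trapezoid in log space (g is peak-normalized)
gmw_inversion_constant <- function(params) {
  wp <- gmw_peak_omega(params)
  v <- seq(-6, 4, by = 1e-4)
  g <- gmw_eval(wp * exp(v), params)
  sum((g[-1] + g[-length(g)]) / 2) * 1e-4
}

#' Invert a (synchrosqueezed) CWT scalogram
#'
#' One-sided Morlet-style reconstruction: the real part of the scale (or
#' frequency-bin) sum, weighted by the log-scale spacing and the wavelet
#' admissibility constant. Exact up to edge effects and the lost DC
#' component for signals band-limited within the scale range; for
#' synchrosqueezed input the complex-sum accumulator carried on the
#' scalogram is summed instead, which reduces to the same formula.
#'
#' @param scal A `scalogram` from [cwt()] or [synchrosqueeze()].
#' @param params The forward transform's [wavelet_params()].
#' @return Numeric vector, one value per scalogram column.
#' @export
invert_cwt <- function(scal, params = scal$params) {
  if (nrow(scal$values) != length(scal$scales)) {
    rlang::abort("scalogram rows do not match its scale axis",
                 class = "ramangrade_validation")
  }
  if (!identical(c(params$gamma, params$beta, as.integer(params$nv)),
                 c(scal$params$gamma, scal$params$beta, as.integer(scal$params$nv)))) {
    rlang::abort("params do not match the scalogram's forward transform",
                 class = "ramangrade_validation")
  }
  C <- gmw_inversion_constant(params)
  dlna <- log(2) / params$nv
  vals <- if (scal$kind == "ssq" && !is.null(scal$csum)) scal$csum else scal$values
  (2 / C) * dlna * colSums(Re(vals))
}

# ---- rendering --------------------------------------------------------------

#' Classic JET colormap
#'
#' The 64-anchor piecewise-linear blue-cyan-yellow-red map, interpolated
#' linearly between anchors so renders are identical across platforms.
#'
#' @param x Numeric values in `[0, 1]`.
#' @return Matrix `length(x) x 3` of RGB values in `[0, 1]`.
#' @export
jet_colormap <- function(x) {
  t_anchor <- seq(0, 1, length.out = 64L)
  clamp01 <- function(v) pmin(pmax(v, 0), 1)
  anchors <- cbind(
    r = clamp01(1.5 - abs(4 * t_anchor - 3)),
    g = clamp01(1.5 - abs(4 * t_anchor - 2)),
    b = clamp01(1.5 - abs(4 * t_anchor - 1))
  )
  x <- pmin(pmax(x, 0), 1)
  cbind(
    approx(t_anchor, anchors[, 1], xout = x)$y,
    approx(t_anchor, anchors[, 2], xout = x)$y,
    approx(t_anchor, anchors[, 3], xout = x)$y
  )
}

#' Bilinear resize of a matrix or RGB array
#'
#' @param img Matrix `h x w` or array `h x w x c`.
#' @param out_h,out_w Output size.
#' @return Resized matrix/array.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  one <- function(m) {
    h <- nrow(m); w <- ncol(m)
    yi <- if (out_h == 1L) rep(1, 1) else (seq_len(out_h) - 1) * (h - 1) / (out_h - 1) + 1
    xi <- if (out_w == 1L) rep(1, 1) else (seq_len(out_w) - 1) * (w - 1) / (out_w - 1) + 1
    y0 <- pmin(floor(yi), h - 1L); x0 <- pmin(floor(xi), w - 1L)
    if (h == 1L) y0 <- rep(1L, out_h)
    if (w == 1L) x0 <- rep(1L, out_w)
    fy <- yi - y0; fx <- xi - x0
    y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)
    a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
    c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
    FY <- matrix(fy, out_h, out_w); FX <- matrix(fx, out_h, out_w, byrow = TRUE)
    a * (1 - FY) * (1 - FX) + b * (1 - FY) * FX + c_ * FY * (1 - FX) + d * FY * FX
  }
  if (length(dim(img)) == 3L) {
    out <- array(0, c(out_h, out_w, dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- one(img[, , ch])
    out
  } else {
    one(img)
  }
}

#' Render a scalogram as a 224 x 224 JET RGB image
#'
#' The magnitude is min-max scaled to `[0, 1]` per image and then
#' logarithmically compressed (`log1p(50 x) / log1p(50)`; Raman
#' scalograms are dominated by low-frequency baseline energy), mapped
#' through the classic JET colormap and bilinearly resized. Normalizing
#' before the compression makes the render invariant to positive
#' rescaling of the magnitudes; a constant scalogram maps to the
#' colormap's value-0 color, and the global maximum always renders the
#' endpoint color (dark red).
#'
#' @param scal A `scalogram` (complex or magnitude).
#' @param out_size Output side length (default 224).
#' @return Array `out_size x out_size x 3` with channels in `[0, 1]`,
#'   class `rgb_image`.
#' @export
scalogram_to_rgb <- function(scal, out_size = 224L) {
  mag <- Mod(scal$values)
  if (all(is.na(mag))) {
    rlang::abort("scalogram magnitudes are all NA", class = "ramangrade_validation")
  }
  rng <- range(mag)
  g <- if (rng[2] > rng[1]) {
    log1p(50 * (mag - rng[1]) / (rng[2] - rng[1])) / log1p(50)
  } else {
    mag * 0
  }
  g <- resize_bilinear(g, out_size, out_size)
  cols <- jet_colormap(as.vector(g))
  img <- array(0, c(out_size, out_size, 3L))
  img[, , 1] <- cols[, 1]; img[, , 2] <- cols[, 2]; img[, , 3] <- cols[, 3]
  structure(img, class = c("rgb_image", "array"))
}

#' Write an RGB image to PNG
#' @param img `rgb_image` array with values in `[0, 1]`.
#' @param path Output path.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' Render spectra to stage-2 input images
#'
#' For each spectrum: z-score (if not already normalized), CWT,
#' synchrosqueeze, JET render. This is the 1D-to-2D conversion the
#' cascade applies to samples routed to the second stage.
#'
#' @param x A `raman_spectra` set (normalized or raw; raw input is
#'   normalized first).
#' @param params A [wavelet_params()].
#' @param ssq Apply synchrosqueezing before rendering (default TRUE).
#' @param out_size Image side length.
#' @return List of `rgb_image` arrays, one per spectrum.
#' @export
spectra_to_images <- function(x, params = wavelet_params(), ssq = TRUE,
                              out_size = 224L) {
  if (!"degenerate" %in% names(x$meta)) x <- normalize_spectra(x)
  lapply(seq_len(nrow(x$intensities)), function(i) {
    s <- x$intensities[i, ]
    sc <- cwt(s, params)
    if (ssq) sc <- synchrosqueeze(sc, s, params)
    scalogram_to_rgb(sc, out_size)
  })
}
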