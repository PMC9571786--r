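#' Class activation map of the stage-2 classifier
#'
#' Weights the final convolutional feature maps (7x7 for the default
#' backbone on 224x224 input) by the classification head's weights for
#' the chosen class, then min-max normalizes the map to `[0, 1]`. Needs
#' an architecture whose head is a linear layer on globally pooled
#' feature maps, which all the package's 2D backbones satisfy.
#'
#' @param model A [build_transfer_model()] model.
#' @param image 224x224x3 array.
#' @param class_index Integer column of the head (or a class label if the
#'   model has been trained).
#' @return A `cam_map`: `values` (feature-map-sized matrix in `[0, 1]`)
#'   and `class_index`.
#' @export
compute_cam <- function(model, image, class_index = 1L) {
  layers <- model$net$layers
  types <- vapply(layers, function(l) l$type, "")
  gap_at <- match("gap2d", types)
  if (is.na(gap_at) || types[length(types)] != "dense") {
    rlang::abort("model has no globally pooled feature map feeding a linear head",
                 class = "ramangrade_capability")
  }
  if (is.character(class_index)) {
    class_index <- match(class_index, model$class_levels)
    if (is.na(class_index)) {
      rlang::abort("unknown class label", class = "ramangrade_validation")
    }
  }
  x <- array(normalize_image(image), c(dim(image), 1L))
  for (l in layers[seq_len(gap_at - 1L)]) x <- layer_forward(l, x, FALSE)
  fmap <- x[, , , 1]                      # (h, w, C)
  W <- layers[[length(layers)]]$W         # (C, n_classes)
  cam <- matrix(0, dim(fmap)[1], dim(fmap)[2])
  for (c_ in seq_len(dim(fmap)[3])) {
    cam <- cam + W[c_, class_index] * fmap[, , c_]
  }
  rng <- range(cam)
  cam <- if (rng[2] > rng[1]) (cam - rng[1]) / (rng[2] - rng[1]) else cam * 0
  structure(list(values = cam, class_index = class_index),
            class = "cam_map")
}

gaussian_blur_sigma <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  blur1 <- function(v) {
    n <- length(v)
    padded <- v[pad_idx(n)]
    stats::convolve(padded, rev(kern), type = "filter")
  }
  m <- apply(m, 2, blur1)
  t(apply(t(m), 2, blur1))
}

#' Overlay a CAM heatmap on its source image
#'
#' The map is bilinearly upsampled to the image size, smoothed with a
#' Gaussian (sd 2 pixels), JET-colormapped and alpha-blended over the
#' image.
#'
#' @param cam A [compute_cam()] map.
#' @param image 224x224x3 array in `[0, 1]`.
#' @param alpha Blend weight of the heatmap in `[0, 1]`.
#' @param smooth_sigma Gaussian sd in pixels (0 disables smoothing).
#' @return Blended `rgb_image`.
#' @export
overlay_cam <- function(cam, image, alpha = 0.4, smooth_sigma = 2) {
  d <- dim(image)
  up <- resize_bilinear(cam$values, d[1], d[2])
  if (smooth_sigma > 0) up <- gaussian_blur_sigma(up, smooth_sigma)
  up <- pmin(pmax(up, 0), 1)
  cols <- jet_colormap(as.vector(up))
  heat <- array(0, d)
  heat[, , 1] <- cols[, 1]; heat[, , 2] <- cols[, 2]; heat[, , 3] <- cols[, 3]
  out <- (1 - alpha) * image + alpha * heat
  structure(out, class = c("rgb_image", "array"))
}

#' Map salient CAM columns to wavenumber intervals
#'
#' The scalogram's horizontal axis follows the spectrum's wavenumber
#' axis, so CAM columns correspond (approximately, and here by linear
#' proportion) to wavenumber intervals: column `j` of `m` maps to
#' `[nu_min + (j-1)/m * range, nu_min + j/m * range]`. Columns whose
#' maximum CAM value reaches `threshold` are selected and adjacent
#' selections merged.
#'
#' @param cam A [compute_cam()] map.
#' @param grid The wavenumber grid of the source spectrum.
#' @param threshold Saliency cutoff in `(0, 1)` (default 0.6).
#' @return Tibble with columns `start`, `end` (cm^-1), one row per
#'   merged salient interval.
#' @export
cam_to_wavenumber_interval <- function(cam, grid, threshold = 0.6) {
  if (threshold <= 0 || threshold >= 1) {
    rlang::abort("threshold must lie in (0, 1)", class = "ramangrade_validation")
  }
  m <- ncol(cam$values)
  col_max <- apply(cam$values, 2, max)
  hot <- which(col_max >= threshold)
  if (!length(hot)) return(tibble::tibble(start = numeric(), end = numeric()))
  nu_min <- min(grid); span <- max(grid) - nu_min
  runs <- split(hot, cumsum(c(1, diff(hot) != 1)))
  purrr::map_dfr(runs, function(r) {
    tibble::tibble(start = nu_min + (min(r) - 1) / m * span,
                   end = nu_min + max(r) / m * span)
  })
}
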