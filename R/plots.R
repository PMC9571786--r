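#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot spectra colored by grade
#'
#' @param object A `raman_spectra` set.
#' @param n_max Maximum number of spectra drawn (sampled evenly per grade).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.raman_spectra <- function(object, n_max = 12L, ...) {
  n <- length(object)
  if (n > n_max) {
    idx <- unlist(lapply(split(seq_len(n), object$meta$grade), function(g) {
      g[unique(round(seq(1, length(g), length.out = ceiling(n_max / 3))))]
    }))
    object <- object[sort(idx)]
  }
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$intensity,
                                   group = .data$spectrum_id,
                                   color = .data$grade)) +
    ggplot2::geom_line(alpha = 0.8, linewidth = 0.3) +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "intensity (a.u.)", color = "grade") +
    ggplot2::theme_minimal()
}

#' Plot a scalogram magnitude map
#'
#' @param object A `scalogram`.
#' @param ... Unused.
#' @return A ggplot raster of `log1p` magnitude over position x frequency.
#' @exportS3Method ggplot2::autoplot
autoplot.scalogram <- function(object, ...) {
  df <- tibble::tibble(
    frequency = rep(object$freqs, times = length(object$positions)),
    position = rep(object$positions, each = length(object$freqs)),
    magnitude = as.vector(log1p(Mod(object$values)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$frequency,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position (grid index)", y = "frequency (cycles/sample)",
                  fill = "log1p |W|") +
    ggplot2::theme_minimal()
}

#' Plot training loss curves
#'
#' @param history Tibble with `epoch` and `loss` (a model's `tidy()`
#'   output, or several bound together with a `stage` column).
#' @return A ggplot.
#' @export
plot_training_history <- function(history) {
  p <- ggplot2::ggplot(history, ggplot2::aes(x = .data$epoch, y = .data$loss))
  if ("stage" %in% names(history)) {
    p <- p + ggplot2::aes(color = .data$stage)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean training loss") +
    ggplot2::theme_minimal()
}
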