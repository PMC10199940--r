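# ggplot2 displays for the result objects.

#' Plot cost curves
#'
#' Log-log normalised wall-time against series length, one line per measure.
#'
#' @param object An `eeg_cost_curves` table from [cost_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eeg_cost_curves
#' @export
autoplot.eeg_cost_curves <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(.data$n, .data$time_normalized, colour = .data$measure)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "series length T", y = "time / time(T = first grid point)",
      colour = "measure", title = "Computational cost of the measures"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a wavelet coherence map
#'
#' Time-frequency raster of the coherence in `[0, 1]`.
#'
#' @param object A [wavelet_coherence()] result.
#' @param fs Sampling rate used for the time axis (Hz).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wavelet_coherence
#' @export
autoplot.wavelet_coherence <- function(object, fs = 128, ...) {
  df <- tidyr::expand_grid(
    freq = object$freqs, time = seq_len(ncol(object$coherence)) / fs
  )
  df$coherence <- as.vector(t(object$coherence))
  ggplot2::ggplot(
    df, ggplot2::aes(.data$time, .data$freq, fill = .data$coherence)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Electrode-wise p-value map of a screening table
#'
#' Dot plot of `-log10(p)` per electrode, facetted by band and coloured by
#' measure -- a flat stand-in for the scalp topographies screeners usually
#' draw.
#'
#' @param evaluations An [evaluate_features()] tibble.
#' @return A ggplot.
#' @export
plot_electrode_pvalues <- function(evaluations) {
  ggplot2::ggplot(
    evaluations,
    ggplot2::aes(
      .data$electrode, -log10(.data$p), colour = .data$measure
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = NULL, y = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
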