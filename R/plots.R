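# ggplot2 visualisations of the package's main objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time-frequency map
#'
#' @param object A `tfd_map`.
#' @param trans Fill transformation (`"sqrt"` by default, good for
#'   power-law spectra).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfd_map
#' @export
autoplot.tfd_map <- function(object, trans = "sqrt", ...) {
  d <- tidyr::expand_grid(time = object$times, freq = object$freqs)
  d$energy <- as.vector(t(object$values))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$freq,
                                  fill = pmax(.data$energy, 0))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "energy", trans = trans) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot the channels of an EEG record
#'
#' Channels are stacked with a fixed vertical offset; the trace is
#' decimated for display.
#'
#' @param object An `eeg_record`.
#' @param max_points Display decimation target per channel.
#' @param offset Vertical spacing between channels, microvolts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eeg_record
#' @export
autoplot.eeg_record <- function(object, max_points = 4000, offset = NULL, ...) {
  n <- ncol(object$samples)
  keep <- unique(round(seq(1L, n, length.out = min(n, max_points))))
  offset <- offset %||% max(3 * stats::sd(object$samples), 10)
  nch <- nrow(object$samples)
  d <- purrr::map_dfr(seq_len(nch), function(ch) {
    tibble::tibble(time = (keep - 1L) / object$fs,
                   channel = object$channel_labels[ch],
                   value = object$samples[ch, keep] + (nch - ch) * offset)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::scale_y_continuous(
      breaks = (nch - seq_len(nch)) * offset,
      labels = object$channel_labels) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the AM and IF sub-signals of an epoch
#'
#' @param object An `am_if_pair` from [extract_am_if()].
#' @param ... Unused.
#' @return A ggplot object (two facets).
#' @method autoplot am_if_pair
#' @export
autoplot.am_if_pair <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(time = object$times, value = object$am,
                   signal = "AM (µV)"),
    tibble::tibble(time = object$times, value = object$iff,
                   signal = "IF (Hz)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a tile map
#'
#' @param object A `conf_mat`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conf_mat
#' @export
autoplot.conf_mat <- function(object, ...) {
  d <- tidy.conf_mat(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$reference,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "system grade", y = "reference grade") +
    ggplot2::theme_minimal()
}
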