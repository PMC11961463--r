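#' Scatter plot of the two spectra-curation dimensions
#'
#' Sum intensity versus fraction of passing analytes per (sample, site)
#' measurement, coloured by sample type, with the per-site cutoffs drawn as
#' dashed lines — the static counterpart of the curation scatter used to
#' judge where the cutoffs fall relative to the dense cluster of good
#' measurements and the low-quality tail.
#'
#' @param summaries Spectrum summaries from [summarize_spectra()].
#' @param cutoffs Optional cutoff tibble.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_spectra_curation <- function(summaries, cutoffs = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_glyco("plot_spectra_curation() requires ggplot2",
                "glycocurate_plot")
  }
  dat <- summaries[summaries$has_values, ]
  # keep zero-sum measurements visible on the log axis
  pos <- dat$sum_intensity[dat$sum_intensity > 0]
  floor_val <- if (length(pos) > 0) min(pos) / 2 else 1
  dat$sum_intensity <- pmax(dat$sum_intensity, floor_val)
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$sum_intensity, y = 100 * .data$passing_fraction
  )) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sample_type),
                        alpha = 0.7, size = 1.3) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~site, scales = "free_x") +
    ggplot2::labs(x = "sum intensity of passing analytes (a.u.)",
                  y = "passing analytes (%)", colour = "sample type") +
    ggplot2::theme_bw()
  if (!is.null(cutoffs)) {
    finite <- cutoffs[is.finite(cutoffs$intensity_cutoff) |
                        is.finite(cutoffs$fraction_cutoff), ]
    if (nrow(finite) > 0) {
      p <- p +
        ggplot2::geom_vline(data = finite,
                            ggplot2::aes(xintercept = .data$intensity_cutoff),
                            linetype = "dashed") +
        ggplot2::geom_hline(data = finite,
                            ggplot2::aes(yintercept =
                                           100 * .data$fraction_cutoff),
                            linetype = "dashed")
    }
  }
  p
}

#' Bar chart of analyte passing frequencies
#'
#' Relative frequency with which each analyte-charge combination passes the
#' quality criteria, per scope (biological group or whole dataset), with
#' the minimum-frequency cutoff as a dashed line.
#'
#' @param freq Frequency table from [passing_frequency()].
#' @param min_freq Optional minimum frequency for inclusion.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_analyte_frequencies <- function(freq, min_freq = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_glyco("plot_analyte_frequencies() requires ggplot2",
                "glycocurate_plot")
  }
  freq$entry <- paste0(freq$glycan, " (", freq$charge, "+)")
  p <- ggplot2::ggplot(freq, ggplot2::aes(
    x = .data$entry, y = 100 * .data$frequency
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_grid(scope ~ site) +
    ggplot2::labs(x = NULL, y = "passing frequency (%)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  if (!is.null(min_freq)) {
    p <- p + ggplot2::geom_hline(yintercept = 100 * min_freq,
                                 linetype = "dashed", colour = "red")
  }
  p
}
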