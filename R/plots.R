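#' Ratio bar plot for feature-class enrichment
#'
#' One bar per feature class showing the ratio of the observed candidate
#' overlap count to the null-ensemble mean, with a dashed reference line at
#' the no-enrichment ratio of 1 and an asterisk over classes significant
#' after multiplicity correction.
#'
#' @param object An `nmisv_enrichment` result from [enrich_features()] or
#'   [enrich_exact()].
#' @param alpha Significance level applied to the adjusted p (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nmisv_enrichment
#' @export
autoplot.nmisv_enrichment <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$sig <- !is.na(df$p_adj) & df$p_adj < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_label, y = .data$ratio,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$sig, "*", "")),
                       vjust = -0.4, size = 6) +
    ggplot2::labs(x = NULL, y = "observed / null-mean overlap ratio",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of per-locus NMI frequencies
#'
#' @param nmi An NMI table from [nmi_frequencies()].
#' @param min_freq Optional vertical reference line (e.g. the 0.15 filter).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_nmi_spectrum <- function(nmi, min_freq = NULL, bins = 60) {
  df <- filter(as_tibble(nmi), !is.na(.data$nmi_freq), .data$nmi_freq > 0)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$nmi_freq)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(x = "per-locus NMI frequency", y = "loci") +
    ggplot2::theme_minimal()
  if (!is.null(min_freq)) {
    gg <- gg + ggplot2::geom_vline(xintercept = min_freq,
                                   linetype = "dashed")
  }
  gg
}
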