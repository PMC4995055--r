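# ggplot2 views of the main result types. Plots are conveniences and
# never part of any numeric analysis path.

#' RSCU bar chart by codon family
#'
#' Stacked bars per amino-acid family, the conventional display of
#' relative synonymous codon usage.
#'
#' @param profile A [codon_profile()].
#' @return A ggplot object.
#' @export
plot_rscu <- function(profile) {
  d <- as_tibble(profile)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$aa, y = .data$rscu,
                                  fill = .data$codon)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.1,
                      show.legend = FALSE) +
    ggplot2::labs(x = "Codon family (amino acid)", y = "RSCU") +
    ggplot2::theme_minimal()
}

#' @method autoplot codon_profile
#' @export
autoplot.codon_profile <- function(object, ...) plot_rscu(object)

#' Ka/Ks panel bar chart
#'
#' @param panel Tibble from [kaks_panel()].
#' @return A ggplot object with a dashed line at Ka/Ks = 1, the
#'   neutral-evolution boundary.
#' @export
plot_kaks <- function(panel) {
  ggplot2::ggplot(panel, ggplot2::aes(x = stats::reorder(.data$gene,
                                                         -.data$mean_ratio),
                                      y = .data$mean_ratio,
                                      fill = .data$selection)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "mean Ka/Ks", fill = "selection") +
    ggplot2::theme_minimal()
}

#' @method autoplot cr_report
#' @export
autoplot.cr_report <- function(object, ...) {
  d <- object$segments
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end + 1,
                                    ymin = 0, ymax = 1, fill = .data$class)) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "Position in control region (bp)", y = NULL,
                  fill = "element") +
    ggplot2::theme_minimal()
}
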