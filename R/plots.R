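#' Volcano plot of a differential-expression table
#'
#' @param object A `de_table`.
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 adjusted p, faceted by
#'   stage, SDE genes highlighted.
#' @export
autoplot.de_table <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       neglog_p = -log10(pmax(.data$adj_p, 1e-300)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc, y = .data$neglog_p,
                                    colour = .data$sde)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#B2182B"),
                                 name = "SDE") +
    ggplot2::facet_wrap(~stage, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
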