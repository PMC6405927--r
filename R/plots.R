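#' Plot the posterior of the coancestry coefficients
#'
#' Density of the retained posterior draws of each population's drift
#' coefficient theta.
#'
#' @param object A `coancestry_posterior`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coancestry_posterior
#' @export
autoplot.coancestry_posterior <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$theta,
                                 fill = .data$population)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = expression(theta), y = "posterior density",
                  fill = "population") +
    ggplot2::theme_minimal()
}

#' Histogram of H statistics
#'
#' Under pure drift the H statistic is approximately uniform; an excess near
#' 1 indicates transcripts whose population divergence exceeds the drift
#' null.
#'
#' @param object An `h_test` result.
#' @param threshold Selection threshold drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot h_test
#' @export
autoplot.h_test <- function(object, threshold = 0.95, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$h)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "H", y = "transcripts") +
    ggplot2::theme_minimal()
}

#' Heterozygosity-FST outlier plot
#'
#' Observed SNPs against the simulated neutral envelope; balancing outliers
#' fall below, diversifying above.
#'
#' @param object An `outlier_scan` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot outlier_scan
#' @export
autoplot.outlier_scan <- function(object, ...) {
  env <- attr(object, "envelope")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$he, y = .data$fst,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(
      balancing = "cyan3", diversifying = "deeppink3",
      neutral = "grey60")) +
    ggplot2::labs(x = expression(H[e]), y = expression(F[ST]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-step marginal counts of a flow table
#'
#' Bar panels of the node occupancies of the four steps (alluvial rendering
#' itself is left to external tools; [write_flow()] emits a loadable CSV).
#'
#' @param flow_table A [build_flow()] result.
#' @return A ggplot.
#' @export
plot_flow_marginals <- function(flow_table) {
  stopifnot(inherits(flow_table, "flow_table"))
  long <- flow_table$flow |>
    tidyr::pivot_longer(dplyr::starts_with("step"), names_to = "step",
                        values_to = "node")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$node)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::facet_wrap(~step, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "DETs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
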