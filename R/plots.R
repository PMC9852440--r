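#' Heatmap of phenotypic correlations
#'
#' @param cors Output of [correlation_matrix_fdr()].
#' @return A ggplot object: media-use measures against mental-health
#'   measures, tiles coloured by the correlation, FDR-significant cells
#'   labelled.
#' @export
plot_correlation_heatmap <- function(cors) {
  cors$label <- ifelse(!is.na(cors$p_fdr) & cors$p_fdr < 0.05,
                       sprintf("%.2f*", cors$r), sprintf("%.2f", cors$r))
  ggplot2::ggplot(cors, ggplot2::aes(x = .data$var_right, y = .data$var_left,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  caption = "* FDR-adjusted p < 0.05") +
    ggplot2::theme_minimal()
}

#' Stacked bars of the A/C/E decomposition of phenotypic correlations
#'
#' @param fits A named list of `biv_fit` objects (names label the trait
#'   pairs).
#' @return A ggplot object showing the proportion of each phenotypic
#'   correlation mediated by genetic, shared-environmental and
#'   nonshared-environmental covariance.
#' @export
plot_decomposition_bars <- function(fits) {
  d <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(pair = nm,
               component = factor(c("A", "C", "E"), levels = c("E", "C", "A")),
               proportion = c(f$prop_a, f$prop_c, f$prop_e))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$proportion,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(A = "#1b9e77", C = "#7570b3",
                                          E = "#d95f02")) +
    ggplot2::labs(x = NULL, y = "proportion of phenotypic correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Forest-style plot of the three Gsens scenarios
#'
#' @param scenarios The `table` element of [scenario_analysis()].
#' @return A ggplot object: adjusted exposure-outcome effect per scenario
#'   (observed score in red, SNP-heritability scenario in blue,
#'   twin-heritability scenario in green) with +-1.96 SE bars.
#' @export
plot_gsens_scenarios <- function(scenarios) {
  scenarios$scenario <- factor(scenarios$scenario,
                               levels = c("observed", "snp_h2", "twin_h2"))
  ggplot2::ggplot(scenarios,
                  ggplot2::aes(x = .data$scenario, y = .data$b_adjusted,
                               colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$b_adjusted - 1.96 * .data$se_adjusted,
      ymax = .data$b_adjusted + 1.96 * .data$se_adjusted), width = 0.15) +
    ggplot2::scale_colour_manual(values = c(observed = "#d62728",
                                            snp_h2 = "#1f77b4",
                                            twin_h2 = "#2ca02c"),
                                 guide = "none") +
    ggplot2::labs(x = NULL,
                  y = "adjusted exposure-outcome effect (Bxy)") +
    ggplot2::theme_minimal()
}
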