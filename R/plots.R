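#' Plot a PMF profile
#'
#' Free energy against the reaction coordinate, with stage boundaries
#' marked.
#'
#' @param profile A `pmf_profile`.
#' @return A ggplot object.
#' @export
plot_pmf <- function(profile) {
  df <- data.frame(z = profile$grid, fe = profile$free_energy)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$fe)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "reaction coordinate z (Å)",
                  y = "free energy (kcal/mol)") +
    ggplot2::theme_minimal()
  if (length(profile$stage_boundaries)) {
    p <- p + ggplot2::geom_vline(
      xintercept = profile$grid[profile$stage_boundaries],
      linetype = "dotted", colour = "grey60")
  }
  p
}

#' Plot an acyl-chain order-parameter profile
#'
#' @param profile Output of [order_parameter()].
#' @return A ggplot object.
#' @export
plot_order_parameter <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$carbon, y = .data$mean_scd)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_scd - .data$sd_scd,
      ymax = .data$mean_scd + .data$sd_scd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "tail carbon index", y = expression(S[CD])) +
    ggplot2::theme_minimal()
}

#' Heatmap of residue-lipid occupancy
#'
#' @param table Output of [residue_occupancy()].
#' @return A ggplot object.
#' @export
plot_occupancy <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = factor(.data$residue),
                                      y = .data$group,
                                      fill = .data$occupancy_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 limits = c(0, 100),
                                 name = "occupancy (%)") +
    ggplot2::labs(x = "peptide residue", y = NULL) +
    ggplot2::theme_minimal()
}
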