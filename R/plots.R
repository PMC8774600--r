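#' Plot a RISK21-style exposure/toxicity matrix
#'
#' Draws each analyte's exposure band (P50 to P97.5 ADD) against its
#' toxicity band (POD range) on log10 axes, colored by classification.
#' A convenience visualization; the classifications themselves come from
#' [risk21_classify()].
#'
#' @param risk21 tibble from [risk21_table()].
#' @return A ggplot object.
#' @export
plot_risk21 <- function(risk21) {
  ggplot2::ggplot(risk21,
                  ggplot2::aes(x = .data$exposure_high, y = .data$tox_low,
                               color = .data$classification)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$exposure_low, xmax = .data$exposure_high),
      height = 0) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$tox_low, ymax = .data$tox_high)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte)) +
    ggplot2::labs(x = "estimated exposure (mg/kg bw/day)",
                  y = "toxicity band (mg/kg bw/day)",
                  color = "concern") +
    ggplot2::theme_minimal()
}

#' Plot a TTC screen
#'
#' Exposure per age group against the Cramer-class threshold line.
#'
#' @param ttc tibble from [ttc_table()].
#' @return A ggplot object.
#' @export
plot_ttc <- function(ttc) {
  ggplot2::ggplot(ttc, ggplot2::aes(x = .data$age_group,
                                    y = .data$add_mg_kg_day,
                                    fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold_mg_kg_day),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte)) +
    ggplot2::labs(x = "age group", y = "exposure (mg/kg bw/day)") +
    ggplot2::theme_minimal()
}
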