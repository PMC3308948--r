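#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot lineage-averaged growth curves
#'
#' OD600 against time, averaged over all wells of each lineage at each time
#' point (the way plate experiments are usually displayed), with the control
#' lineage dashed when identifiable.
#'
#' @param curves Long growth table (`lineage`, `time`, `od`, ...).
#' @param control Optional control lineage id drawn dashed.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(curves, control = NULL) {
  avg <- dplyr::summarise(
    dplyr::group_by(dplyr::as_tibble(curves), .data$lineage, .data$time),
    od = mean(.data$od), .groups = "drop")
  avg$role <- if (is.null(control)) "test"
              else ifelse(avg$lineage == control, "control", "test")
  ggplot2::ggplot(avg, ggplot2::aes(.data$time, .data$od,
                                    colour = .data$lineage,
                                    linetype = .data$role)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_linetype_manual(values = c(test = "solid",
                                              control = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "time (h)", y = expression(OD[600]),
                  colour = "lineage") +
    ggplot2::theme_minimal()
}

#' Relative-fitness plot for a lineage summary
#'
#' Relative `mu_max` and relative TTI per test lineage (control = 1, dotted
#' line), with an asterisk over contrasts significant at the summary's
#' alpha.
#'
#' @param object A `platefit_summary` from [summarise_fitness()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.platefit_summary <- function(object, ...) {
  ctrl <- attr(object, "control")
  d <- dplyr::filter(tibble::as_tibble(object), .data$lineage != ctrl)
  long <- tidyr::pivot_longer(
    dplyr::transmute(d, .data$experiment, .data$lineage,
                     `relative mu_max` = .data$relative_mu_max,
                     `relative TTI` = .data$relative_tti,
                     sig_mu = .data$significant_mu_max,
                     sig_tti = .data$significant_tti),
    cols = c("relative mu_max", "relative TTI"),
    names_to = "parameter", values_to = "relative")
  long$sig <- ifelse(long$parameter == "relative TTI", long$sig_tti,
                     long$sig_mu)
  ggplot2::ggplot(long, ggplot2::aes(.data$lineage, .data$relative)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30", width = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_text(data = dplyr::filter(long, .data$sig),
                       ggplot2::aes(y = .data$relative), label = "*",
                       vjust = -0.3, size = 6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL,
                  y = "value relative to within-plate control (= 1)") +
    ggplot2::theme_minimal()
}

#' Fitness proxies against a sequence covariate
#'
#' Scatter of relative `mu_max` and relative TTI against one covariate
#' (JTT distance, p-distance or CAI) with the best-fit least-squares line;
#' points can be shaped by an `rna_type` column when present (the Type-A /
#' Type-B RNase P RNA class label).
#'
#' @param data Merged table with `relative_mu_max`, `relative_tti` and the
#'   covariate column; optionally `lineage` (point labels) and `rna_type`.
#' @param covariate Covariate column name (string).
#' @return A ggplot object.
#' @export
plot_fitness_vs_covariate <- function(data, covariate = "jtt_distance") {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(data),
    cols = c("relative_mu_max", "relative_tti"),
    names_to = "parameter", values_to = "relative")
  aes <- ggplot2::aes(.data[[covariate]], .data$relative)
  gg <- ggplot2::ggplot(long, aes) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted")
  gg <- if ("rna_type" %in% names(long)) {
    gg + ggplot2::geom_point(ggplot2::aes(shape = .data$rna_type), size = 2.5)
  } else {
    gg + ggplot2::geom_point(size = 2.5)
  }
  if ("lineage" %in% names(long)) {
    gg <- gg + ggplot2::geom_text(ggplot2::aes(label = .data$lineage),
                                  vjust = -0.8, size = 3)
  }
  gg + ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = covariate,
                  y = "value relative to within-plate control") +
    ggplot2::theme_minimal()
}
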