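# ggplot2 views of scored frames, agreement tables and composition.

#' Mean FVRI against plaque burden
#'
#' Bin means with one-standard-error bars, the burden bins ordered `<20`
#' through `>60`. In cohorts where vessel enlargement fails to keep pace
#' with plaque (`theta < 1`), the curve declines with burden.
#'
#' @param scored Scored frame tibble from [score_frames()].
#'
#' @return A ggplot object.
#' @export
plot_fvri_by_burden <- function(scored) {
  df <- fvri_by_burden(scored)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$burden_bin, y = .data$mean_fvri,
                                   group = 1)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_fvri - .data$sem_fvri,
      ymax = .data$mean_fvri + .data$sem_fvri
    ), colour = "steelblue") +
    ggplot2::labs(x = "Plaque burden (%)", y = "Mean FVRI",
                  title = "FVRI by plaque burden") +
    ggplot2::theme_minimal()
}

#' @describeIn agreement_table Heatmap of the agreement matrix with cell
#'   counts and percentages; concordant cells outlined.
#' @param object A `fvri_agreement`.
#' @export
autoplot.fvri_agreement <- function(object, ...) {
  df <- tidy(object)
  df$fvri_class <- factor(df$fvri_class, levels = rev(fvri_agreement_rows))
  df$classical_class <- factor(df$classical_class, levels = classical_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$classical_class,
                                   y = .data$fvri_class)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$pct), colour = "white") +
    ggplot2::geom_tile(
      data = df[df$concordant, ], fill = NA, colour = "black",
      linewidth = 0.8
    ) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%.1f%%)", .data$n, .data$pct)
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "indianred",
                                 name = "% of lesions") +
    ggplot2::labs(x = "Classical remodeling class",
                  y = "FVRI-based remodeling class",
                  title = sprintf(
                    "Scheme agreement (n = %d; concordance %.1f%%)",
                    object$n, object$concordance_named_pct
                  )) +
    ggplot2::theme_minimal()
}

#' Plaque composition by remodeling class
#'
#' Bar chart of mean tissue percentages per remodeling class with the
#' one-way ANOVA p-value per tissue in the facet label.
#'
#' @param composition Tibble from [composition_by_class()].
#'
#' @return A ggplot object.
#' @export
plot_composition_by_class <- function(composition) {
  df <- composition
  df$panel <- sprintf("%s (p = %.3g)", df$tissue, df$p_value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$mean_pct,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_pct - .data$sd_pct / sqrt(.data$n),
      ymax = .data$mean_pct + .data$sd_pct / sqrt(.data$n)
    ), width = 0.25) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Mean tissue % of plaque") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
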