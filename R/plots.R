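#' Plot a signal table as an ROR forest plot
#'
#' Point estimates with 95% confidence intervals on a log scale, joint
#' signals highlighted.
#'
#' @param object A `cartpv_signals` tibble from [signal_screen()] or
#'   [disproportionality()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cartpv_signals
#' @export
autoplot.cartpv_signals <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$ror), , drop = FALSE]
  df$pt <- stats::reorder(df$pt, df$ror)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$pt)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_lo95,
                                         xmax = .data$ror_hi95),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$joint_signal,
                                     size = .data$n)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey40"),
                                 name = "joint signal") +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL,
                  size = "reports")
}

#' Plot the per-product IC025 matrix as a heatmap
#'
#' Cells with fewer than the minimum cases are blank; positive IC025
#' (a safety signal) is shaded warm.
#'
#' @param object A [per_drug_ic_matrix()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cartpv_ic_matrix
#' @export
autoplot.cartpv_ic_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$product, y = .data$pt,
                                   fill = .data$ic025)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$ic025)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2c7bb6", mid = "white",
                                  high = "#d7191c", midpoint = 0,
                                  name = "IC025") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot annual pulmonary-event report counts
#'
#' @param annual A [counts_by_year()] result (or a `cartpv_run`).
#' @return A ggplot object.
#' @export
plot_annual_counts <- function(annual) {
  if (inherits(annual, "cartpv_run")) annual <- annual$annual
  ggplot2::ggplot(annual, ggplot2::aes(x = factor(.data$year),
                                       y = .data$n_pae_reports)) +
    ggplot2::geom_col(fill = "#2c7bb6") +
    ggplot2::labs(x = "FDA receipt year", y = "Pulmonary AE reports")
}

#' Plot time-to-onset distributions per product
#'
#' @param tto A [time_to_onset()] result (or a `cartpv_run`).
#' @return A ggplot object.
#' @export
plot_tto <- function(tto) {
  if (inherits(tto, "cartpv_run")) tto <- tto$tto
  df <- tto[tto$reason == "ok" & !is.na(tto$product), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$product, y = .data$days)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::geom_hline(yintercept = 30, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "Days from therapy start to onset")
}

#' Plot per-product case-fatality proportions
#'
#' @param fatality A [fatality_by_drug()] result (or a `cartpv_run`).
#' @return A ggplot object.
#' @export
plot_fatality <- function(fatality) {
  if (inherits(fatality, "cartpv_run")) fatality <- fatality$fatality
  ggplot2::ggplot(fatality,
                  ggplot2::aes(x = stats::reorder(.data$product,
                                                  -.data$fatality_pct),
                               y = .data$fatality_pct)) +
    ggplot2::geom_col(fill = "#c0392b") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d (%.1f%%)", .data$deaths, .data$pae_cases,
                      .data$fatality_pct)), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Case fatality (%)")
}
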