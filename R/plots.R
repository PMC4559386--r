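#' Plot indifference points with fitted discount curves
#'
#' Draws the sample-mean indifference-point proportions at 3, 6, 9 and 12
#' months with standard-error bars, overlaid with the hyperbolic and
#' quasi-hyperbolic curves fitted to those means.
#'
#' @param ips Indifference table from [estimate_indifference()] (blocks 5-6
#'   are ignored).
#' @return A ggplot object.
#' @export
plot_discount_curve <- function(ips) {
  means <- ips |>
    dplyr::filter(.data$block %in% 1:4) |>
    dplyr::group_by(.data$later_delay) |>
    dplyr::summarise(
      mean_ip = mean(.data$ip_proportion),
      se = stats::sd(.data$ip_proportion) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  hyp <- fit_hyperbolic(means$mean_ip)
  qh <- fit_quasihyperbolic(means$mean_ip)
  grid <- tibble::tibble(t = seq(0.01, 12.5, length.out = 200))
  curves <- dplyr::bind_rows(
    dplyr::mutate(grid, sv = sv_hyperbolic(hyp$k, .data$t),
                  model = "hyperbolic"),
    dplyr::mutate(grid, sv = sv_quasihyperbolic(qh$beta, qh$delta, .data$t),
                  model = "quasi-hyperbolic")
  )
  ggplot2::ggplot(means, ggplot2::aes(x = .data$later_delay,
                                      y = .data$mean_ip)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$t, y = .data$sv,
                                    linetype = .data$model,
                                    colour = .data$model)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ip - .data$se,
                                        ymax = .data$mean_ip + .data$se),
                           width = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Delay (months)",
                  y = "Indifference point (proportion of 20 €)",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a median-split summary
#'
#' Bar chart of cell means with standard-error bars for a
#' [median_split_summary()] table: high versus low scorers by gender.
#'
#' @param split_summary Output of [median_split_summary()].
#' @param outcome_label Y-axis label.
#' @return A ggplot object.
#' @export
plot_median_split <- function(split_summary, outcome_label = "Outcome") {
  ggplot2::ggplot(split_summary,
                  ggplot2::aes(x = .data$gender, y = .data$mean,
                               fill = .data$split)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9), width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.9), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = outcome_label, fill = "Score") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a regression hierarchy
#'
#' Standardized betas with 95% confidence bars, one panel per model.
#'
#' @param object A `dd_hierarchy` from [fit_model_hierarchy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dd_hierarchy
#' @export
autoplot.dd_hierarchy <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(model = paste("model", .data$model))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "Standardized beta", y = NULL,
                  title = paste("Outcome:", object$outcome)) +
    ggplot2::theme_minimal()
}
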