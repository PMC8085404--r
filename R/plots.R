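#' Waterfall plot of predicted subtype probabilities
#'
#' One bar per sample, ordered by predicted LUAD probability, coloured by
#' the call; dashed lines mark the thresholds in use.
#'
#' @param calls Tibble from [classify_samples()] (columns `sample_id`,
#'   `probability`, `call`).
#' @param thresholds Optional [threshold_pair()] to mark.
#' @return A ggplot object.
#' @export
plot_probabilities <- function(calls, thresholds = NULL) {
  df <- dplyr::arrange(calls, .data$probability)
  df$sample_id <- factor(df$sample_id, levels = df$sample_id)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                         y = .data$probability,
                                         fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(LUAD = "#D55E00", LUSC = "#009E73",
                                          INDETERMINATE = "grey60")) +
    ggplot2::labs(x = NULL, y = "P(LUAD)", fill = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(thresholds)) {
    gg <- gg + ggplot2::geom_hline(
      yintercept = c(thresholds$theta_luad, thresholds$theta_lusc),
      linetype = "dashed")
  }
  gg
}

#' ROC curve with the c-statistic in the caption
#'
#' @inheritParams c_statistic
#' @return A ggplot object.
#' @export
plot_roc <- function(p, y) {
  pts <- roc_points(p, y)
  auc <- c_statistic(p, y)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  caption = sprintf("c-statistic = %.3f", auc)) +
    ggplot2::theme_minimal()
}

#' Plot a NOS profile: ECDFs and kernel densities side by side
#'
#' @param object A [nos_profile()].
#' @param ... Unused.
#' @return A ggplot object (faceted: cumulative and density panels).
#' @method autoplot nos_profile
#' @export
autoplot.nos_profile <- function(object, ...) {
  ecdf_df <- dplyr::mutate(object$ecdf, panel = "cumulative",
                           yval = .data$F)
  dens_df <- dplyr::mutate(object$density, panel = "density",
                           yval = .data$y)
  df <- dplyr::bind_rows(ecdf_df[, c("group", "x", "yval", "panel")],
                         dens_df[, c("group", "x", "yval", "panel")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$yval,
                                   colour = .data$group)) +
    ggplot2::geom_step(data = ~ dplyr::filter(.x, .data$panel == "cumulative"),
                       direction = "hv") +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$panel == "density")) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(LUAD = "#D55E00", LUSC = "#009E73",
                                            NOS = "grey40")) +
    ggplot2::labs(x = "P(LUAD)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Convergence of the resampling estimates
#'
#' Running mean and 95% confidence band of complexity, accuracy and alpha
#' against the number of resampling iterations.
#'
#' @param convergence Tibble from [convergence_summary()].
#' @return A ggplot object.
#' @export
plot_convergence <- function(convergence) {
  ggplot2::ggplot(convergence, ggplot2::aes(x = .data$checkpoint,
                                            y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25, fill = "#0072B2") +
    ggplot2::geom_line(colour = "#0072B2") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "resampling iterations", y = "running estimate") +
    ggplot2::theme_minimal()
}
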