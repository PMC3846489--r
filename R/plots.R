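#' Plot an LD decay curve
#'
#' @param curve An `ld_decay` tibble (or several bound together with a
#'   `breed` column).
#' @param colour Optional column name used to colour curves.
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(curve, colour = NULL) {
  mid <- (curve$bin_start_bp + curve$bin_end_bp) / 2
  d <- dplyr::mutate(curve, distance_kb = mid / 1000)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_kb,
                                       y = .data$mean_r2))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::labs(x = "Distance between SNPs (kb)",
                  y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' Plot per-breed imputation error against reference population size
#'
#' @param data A tibble with columns `train_size`, `error_rate_pct` and
#'   optionally `type` (dairy/beef), e.g. [breed_factors()].
#' @return A ggplot object.
#' @export
plot_error_vs_size <- function(data) {
  aes <- if ("type" %in% names(data)) {
    ggplot2::aes(x = .data$train_size, y = .data$error_rate_pct,
                 colour = .data$type)
  } else {
    ggplot2::aes(x = .data$train_size, y = .data$error_rate_pct)
  }
  ggplot2::ggplot(data, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.4) +
    ggplot2::labs(x = "Reference population size",
                  y = "Allelic imputation error rate (%)") +
    ggplot2::theme_minimal()
}

#' Plot the MAF / imputation-error profile
#'
#' @param profile Output of [maf_error_profile()].
#' @return A ggplot object.
#' @export
plot_maf_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$mean_maf,
                                        y = .data$mean_error,
                                        colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Minor allele frequency (bin mean)",
                  y = "Mean allelic imputation error rate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient plot for a factor regression
#'
#' @param object A `factor_fit`.
#' @param ... Unused.
#' @return A ggplot object showing standardized effects with 95% intervals.
#' @exportS3Method ggplot2::autoplot
autoplot.factor_fit <- function(object, ...) {
  d <- object$coefficients[-1L, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std_error,
                   xmax = .data$estimate + 1.96 * .data$std_error),
      height = 0.15
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Coefficient (error-% per unit)", y = NULL) +
    ggplot2::theme_minimal()
}
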