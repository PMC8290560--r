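#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot weekly variance components and heritability
#'
#' @param object an [trajectory_parameters()] result.
#' @param ... unused.
#' @return A ggplot: variance components and heritability against week of lay.
#' @method autoplot rregg_trajectory
#' @export
autoplot.rregg_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$by_week, c("var_a", "var_pe", "var_e", "h2"),
    names_to = "component", values_to = "value"
  )
  long$component <- factor(long$component,
    levels = c("var_a", "var_pe", "var_e", "h2"),
    labels = c("additive", "permanent env.", "residual", "heritability")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$week, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(
      x = "week of lay", y = NULL,
      title = "Weekly variance components of egg production"
    ) +
    ggplot2::theme_minimal()
}

#' Trace plots of a Gibbs chain
#'
#' @param object an [run_gibbs()] chain.
#' @param parameters optional subset of parameter names (default: diagonal
#'   coefficient variances and residuals).
#' @param ... unused.
#' @return A ggplot of traces, one facet per parameter.
#' @method autoplot rregg_chain
#' @export
autoplot.rregg_chain <- function(object, parameters = NULL, ...) {
  draws <- object$draws
  parameters <- parameters %||% intersect(
    c("C11", "C22", "C33", "C44", "P11", "P22", paste0("r", seq_len(object$n_periods))),
    names(draws)
  )
  long <- tidyr::pivot_longer(
    draws[, c("sample", parameters)], -"sample",
    names_to = "parameter", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "saved sample", y = NULL, title = "Gibbs chain traces") +
    ggplot2::theme_minimal()
}

#' Plot weekly validation accuracies
#'
#' @param object an [validate_accuracy()] result.
#' @param statistic `"acc_corr"` or `"nu"`.
#' @param ... unused.
#' @return A ggplot of the chosen statistic by week and method.
#' @method autoplot rregg_validation
#' @export
autoplot.rregg_validation <- function(object, statistic = c("acc_corr", "nu"), ...) {
  statistic <- match.arg(statistic)
  lab <- if (statistic == "acc_corr") {
    "correlation-based accuracy"
  } else {
    "Mendelian-sampling variance ratio"
  }
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$week, .data[[statistic]], colour = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "week of lay", y = lab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot EBV trajectories of selected animals
#'
#' @param fit an [fit_rr()] object.
#' @param animals animal labels to draw (default: the 8 highest cumulative
#'   EBVs).
#' @return A ggplot of weekly EBV curves.
#' @export
plot_ebv_trajectories <- function(fit, animals = NULL) {
  ebv <- ebv_trajectory(fit)
  if (is.null(animals)) {
    animals <- ebv$animal[order(-ebv$cumulative)][seq_len(min(8, nrow(ebv)))]
  }
  long <- tidy(fit)
  long <- dplyr::filter(long, .data$animal %in% animals)
  ggplot2::ggplot(long, ggplot2::aes(.data$week, .data$ebv, colour = .data$animal)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "week of lay", y = "EBV (eggs/week)",
      title = "Estimated breeding-value trajectories"
    ) +
    ggplot2::theme_minimal()
}
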