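#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_step facet_wrap labs theme_minimal scale_y_log10 coord_flip
#'   geom_hline
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' @param object A `circuit_trajectory` from [simulate_circuit()].
#' @param ... Unused.
#' @return A ggplot: concentration against time, one line per species.
#' @export
autoplot.circuit_trajectory <- function(object, ...) {
  ggplot(object, aes(.data$time, .data$value, colour = .data$species)) +
    geom_line() +
    labs(x = "time", y = "concentration", colour = NULL) +
    theme_minimal()
}

#' Plot a risk table
#'
#' @param object A `risk_table` from [rank_experiments()].
#' @param top Number of lowest-risk experiments to show (default 10).
#' @param ... Unused.
#' @return A ggplot: expected risk per candidate experiment, lowest first,
#'   with the baseline risk as a dashed line.
#' @export
autoplot.risk_table <- function(object, top = 10, ...) {
  df <- head(object, top)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot(df, aes(.data$label, .data$risk)) +
    geom_col(fill = "steelblue") +
    geom_hline(
      yintercept = attr(object, "baseline"),
      linetype = "dashed", colour = "grey40"
    ) +
    coord_flip() +
    labs(x = NULL, y = "expected risk (dashed: baseline)") +
    theme_minimal()
}

#' Plot marginal posterior distributions
#'
#' @param object A `posterior_sample`.
#' @param ... Unused.
#' @return A ggplot of per-parameter marginal histograms on the log scale.
#' @export
autoplot.posterior_sample <- function(object, ...) {
  df <- tidy(object, log_scale = TRUE)
  ggplot(df, aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    facet_wrap(~parameter, scales = "free") +
    labs(x = "log parameter value", y = "draws") +
    theme_minimal()
}

#' Plot a strategy comparison
#'
#' @param object A `strategy_comparison` from [compare_strategies()].
#' @param ... Unused.
#' @return A ggplot: true risk against budget spent, one line per repeat,
#'   faceted by strategy, log-scaled risk axis.
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  ggplot(object, aes(.data$budget_spent, .data$true_risk,
    group = .data$rep, colour = factor(.data$rep)
  )) +
    geom_step() +
    geom_point(size = 1) +
    scale_y_log10() +
    facet_wrap(~strategy) +
    labs(
      x = "budget spent (credits)", y = "true risk",
      colour = "repeat"
    ) +
    theme_minimal()
}
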