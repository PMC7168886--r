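#' Plot a power-versus-cost trade-off grid
#'
#' Power to call one gene differential against the cost of the design
#' relative to the reference; one point per design, coloured by strategy.
#'
#' @param object A [tradeoff_grid()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pool_tradeoff <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$relative_cost,
                                       y = .data$power,
                                       colour = .data$strategy)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$parameter),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::scale_x_continuous(labels = scales_percent) +
    ggplot2::labs(x = "cost relative to reference", y = "power",
                  colour = NULL,
                  title = "Power vs relative cost of cost-saving strategies") +
    ggplot2::theme_minimal()
}

# tiny percent formatter; avoids depending on the scales package directly
scales_percent <- function(x) paste0(round(100 * x), "%")

#' Plot FDR-TPR trade-off curves
#'
#' One curve per scenario over the nominal FDR grid; the point at the 5%
#' nominal level is highlighted.
#'
#' @param object A [fdr_tpr()] curve, or the `curves` element of a
#'   [evaluate_scenarios()] result (with a `scenario` column).
#' @param highlight Nominal level to mark with a solid point (default
#'   0.05; `NULL` to disable).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pool_fdr_tpr <- function(object, highlight = 0.05, ...) {
  has_scenario <- "scenario" %in% names(object)
  aes <- if (has_scenario) {
    ggplot2::aes(x = .data$fdr, y = .data$tpr, colour = .data$scenario)
  } else {
    ggplot2::aes(x = .data$fdr, y = .data$tpr)
  }
  p <- ggplot2::ggplot(object, aes) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "actual FDR", y = "TPR (sensitivity)",
                  title = "FDR-TPR trade-off over nominal FDR levels") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    near <- object[abs(object$nominal - highlight) < 1e-9, , drop = FALSE]
    if (nrow(near) > 0) p <- p + ggplot2::geom_point(data = near, size = 2.5)
  }
  p
}

#' Plot a scenario ranking
#'
#' Composite performance score per scenario (bars, best first), with the
#' relative data-generation cost overlaid as points.
#'
#' @param object A [performance_score()] result or a
#'   [evaluate_scenarios()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pool_ranking <- function(object, ...) {
  d <- as_tibble(object)
  d$scenario <- stats::reorder(d$scenario, -d$rank)
  rel_cost <- d$cost / max(d$cost)
  rng <- range(d$score)
  d$cost_scaled <- rng[1] + rel_cost * diff(rng)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scenario, y = .data$score)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cost_scaled),
                        colour = "black", size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "composite performance score",
                  title = "Scenario ranking (points: relative cost)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pool_ranking
#' @export
autoplot.pool_eval <- function(object, ...) {
  stop_if_not(!is.null(object$ranking),
    "evaluation has no ranking (fewer than two scenarios)")
  autoplot.pool_ranking(object$ranking, ...)
}

#' Closed-form pooled variance across pool sizes
#'
#' Evaluates [pooled_variance()] over a range of pool sizes and plots the
#' decay of the pooled-library variance with growing pools.
#'
#' @param pop A [gene_population()].
#' @param q Pool sizes to evaluate (default 1 to 6).
#' @param sigma2_eps Technical noise variance.
#' @return A ggplot object.
#' @export
plot_pooled_variance <- function(pop, q = 1:6, sigma2_eps = 0) {
  d <- tibble(q = q, variance = pooled_variance(pop, q, sigma2_eps))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$variance)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "pool size q", y = "Var(pooled expression)",
                  title = "Pooling shrinks within-group variance") +
    ggplot2::theme_minimal()
}
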