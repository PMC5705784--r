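# Quick-look ggplot2 figures for the main result types.

#' Plot a decay fit
#'
#' Observed points with the fitted decay curve overlaid; longitudinal
#' plateau fits get a dashed horizontal line at the survival plateau.
#'
#' @param object A `decay_fit`.
#' @param n_curve Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, n_curve = 200, ...) {
  rng <- range(object$data$t)
  curve <- tibble::tibble(t = seq(rng[1], rng[2], length.out = n_curve))
  curve$value <- predict(object, curve$t)
  lab <- if (object$model == "plateau_decay") {
    sprintf("half-life %.2f d, plateau %.1f%%, R² = %.3f",
            object$half_life, object$plateau_pct, object$r_squared)
  } else {
    sprintf("half-life %.3g d, R² = %.3f", object$half_life,
            object$r_squared)
  }
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "#2166ac") +
    ggplot2::labs(x = "time (days)", y = "BrdU+ cells", subtitle = lab) +
    ggplot2::theme_minimal()
  if (object$model == "plateau_decay") {
    p <- p + ggplot2::geom_hline(yintercept = object$params[["plateau"]],
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Simulated versus experimental population means
#'
#' @param records Simulated cohort tibble from [simulate_cohort()].
#' @param summaries Experimental group-summary tibble.
#' @return A ggplot object comparing means per age and population.
#' @export
plot_simulation_fit <- function(records, summaries) {
  dev <- deviation_from_experiment(records, summaries)
  cells <- attr(dev, "by_cell")
  cells$population <- factor(cells$population,
                             levels = c("n2h", "n2d", "n4d", "n10d", "n30d",
                                        "n_neun", "n_gfap"))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$experimental,
                                      y = .data$simulated,
                                      colour = factor(.data$age_months))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "experimental mean", y = "simulated mean",
                  colour = "age (m)",
                  subtitle = sprintf("mean deviation %.1f%%",
                                     dev$deviation_pct)) +
    ggplot2::theme_minimal()
}

#' Plot neurogenic and astrogenic yields across age
#'
#' @param yield_table Tibble from [yields_by_age()] or
#'   [yields_from_simulation()] (needs `age_months`).
#' @return A ggplot object.
#' @export
plot_yields <- function(yield_table) {
  long <- yield_table |>
    tidyr::pivot_longer(c("neuronal_yield", "astrocytic_yield"),
                        names_to = "lineage", values_to = "yield") |>
    dplyr::mutate(lineage = sub("_yield", "", .data$lineage))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_months, y = .data$yield,
                                     colour = .data$lineage)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "age (months)", y = "yield (30 d cells per 2 h cell)") +
    ggplot2::theme_minimal()
}

#' Plot an allocation search trace
#'
#' @param result A [find_allocation()] result (uses its `"trace"`
#'   attribute).
#' @return A ggplot object of evaluated (p, ratio) pairs in search order.
#' @export
plot_search_trace <- function(result) {
  trace <- attr(result, "trace")
  trace$step <- seq_len(nrow(trace))
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$p, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = result$target_ratio,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_path(alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$step)) +
    ggplot2::labs(x = "neuron share of extra survival (p)",
                  y = "neuron-to-astrocyte ratio", colour = "step") +
    ggplot2::theme_minimal()
}
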