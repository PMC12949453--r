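# ggplot2 views of the result tables. Each takes the tidy table its
# corresponding analysis function returns.

#' Heatmap of rank frequencies
#'
#' @param tallies Output of [tabulate_ranks()] or [weighted_scores()].
#' @return A ggplot object: drugs by rank position, filled by count.
#' @export
plot_rank_heatmap <- function(tallies) {
  long <- tidyr::pivot_longer(tallies, dplyr::starts_with("eta"),
                              names_to = "position", values_to = "count")
  long$position <- as.integer(sub("eta", "", long$position))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$position),
                                     y = stats::reorder(.data$drug,
                                                        .data$count *
                                                          (.data$position == 1)),
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick",
                                  midpoint = stats::median(long$count)) +
    ggplot2::labs(x = "Rank position", y = NULL, fill = "Count") +
    ggplot2::theme_minimal()
}

#' Bar chart of weighted preference scores
#'
#' @param scores Output of [weighted_scores()].
#' @return A ggplot object.
#' @export
plot_weighted_scores <- function(scores) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = stats::reorder(.data$drug,
                                                  .data$weighted_score),
                               y = .data$weighted_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Weighted preference score (4/3/2/1)") +
    ggplot2::theme_minimal()
}

#' Bar chart of attribute relative importance
#'
#' @param importance Output of [relative_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = stats::reorder(.data$attribute,
                                                  .data$share),
                               y = .data$share)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative importance (%)") +
    ggplot2::theme_minimal()
}

#' Coefficient (marginal utility) plot for a fitted choice model
#'
#' Point estimates with 95% confidence intervals for the mean utilities,
#' relative to the reference level of each attribute.
#'
#' @param object A `mixlogit_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixlogit_fit <- function(object, ...) {
  co <- object$coefficients[object$coefficients$type == "mean", ]
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std_error,
                   xmax = .data$estimate + 1.96 * .data$std_error),
      height = 0.2) +
    ggplot2::labs(x = "Marginal utility (vs reference level)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Trace plot of coefficient stability across subsample cuts
#'
#' @param curve A [stability_curve()] result.
#' @return A ggplot object: estimate vs cut size, one line per term.
#' @export
plot_stability <- function(curve) {
  co <- curve$coefficients[curve$coefficients$type == "mean", ]
  ggplot2::ggplot(co, ggplot2::aes(x = .data$cut, y = .data$estimate,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Respondents included", y = "Estimate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
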