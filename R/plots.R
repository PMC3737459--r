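# ggplot2 views of the main result types.

#' Valence-arousal grid of excerpt ratings
#'
#' @param features Feature matrix tibble ([extract_features()]) or any tibble
#'   with `excerpt`, `quadrant`, `mean_valence`, `mean_arousal`.
#' @return A ggplot.
#' @export
plot_va_grid <- function(features) {
  ggplot2::ggplot(
    features,
    ggplot2::aes(
      .data$mean_valence, .data$mean_arousal,
      colour = .data$quadrant, label = .data$excerpt
    )
  ) +
    ggplot2::geom_hline(yintercept = 5, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 5, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, show.legend = FALSE, size = 3) +
    ggplot2::coord_cartesian(xlim = c(1, 9), ylim = c(1, 9)) +
    ggplot2::labs(
      x = "Mean valence (1-9)", y = "Mean arousal (1-9)", colour = "Quadrant"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.physio_mlp <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$epoch, .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      yintercept = object$config$mse_target,
      linetype = 2, colour = "red"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "Training MSE (scaled targets)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.physio_ensemble <- function(object, ...) {
  dat <- object$mean_predictions |>
    tidyr::pivot_longer(
      -"excerpt",
      names_to = c("source", "dimension"), names_sep = "_",
      values_to = "rating"
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(.data$excerpt, .data$rating, fill = .data$source)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~dimension) +
    ggplot2::coord_cartesian(ylim = c(1, 9)) +
    ggplot2::labs(
      x = NULL, y = "Rating (1-9)", fill = NULL,
      title = "Ensemble-mean network predictions vs observed means"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of mean signed contributions per output
#'
#' Trial-mean signed contribution of each feature to each output, with the
#' null threshold (equal-contribution size) marked.
#'
#' @param contributions Tibble from [ensemble_contributions()] or
#'   [milne_contributions()].
#' @param threshold Null threshold to mark (default 1 / n features).
#' @return A ggplot.
#' @export
plot_contributions <- function(contributions, threshold = NULL) {
  means <- contributions |>
    dplyr::group_by(.data$output, .data$input) |>
    dplyr::summarise(contribution = mean(.data$contribution), .groups = "drop")
  if (is.null(threshold)) threshold <- 1 / length(unique(means$input))
  ggplot2::ggplot(
    means,
    ggplot2::aes(
      factor(.data$input, levels = .channels), .data$contribution,
      fill = .data$contribution > 0
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold), linetype = 2) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~ .data$output) +
    ggplot2::labs(
      x = NULL, y = "Signed contribution (|sums| = 1 per output)"
    ) +
    ggplot2::theme_minimal()
}
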