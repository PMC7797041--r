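# ggplot2 views of the main result types. All return a ggplot object so
# callers can restyle or add layers.

#' Plot replicate RLUs per construct
#'
#' Replicate points with the construct mean, against the dashed reference
#' level of 1.0 (no miRNA effect).
#'
#' @param rlu replicate-level RLU tibble.
#' @return a ggplot object.
#' @export
plot_rlu <- function(rlu) {
  stopifnot_cols(rlu, c("construct_label", "rlu"), "rlu")
  means <- summarise(rlu, mean_rlu = mean(.data$rlu), .by = "construct_label")
  ggplot2::ggplot(rlu, ggplot2::aes(x = .data$construct_label, y = .data$rlu)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6, size = 1) +
    ggplot2::geom_point(
      data = means, ggplot2::aes(y = .data$mean_rlu),
      colour = "orange", size = 2.5
    ) +
    ggplot2::labs(x = NULL, y = "RLU (fraction of control)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a validation-rate cut-off grid
#'
#' @param grid tibble from [cutoff_grid()].
#' @return a ggplot object (tile map of rates).
#' @export
plot_cutoff_grid <- function(grid) {
  stopifnot_cols(grid, c("p_max", "rlu_max", "rate"), "grid")
  ggplot2::ggplot(grid, ggplot2::aes(
    x = factor(.data$p_max), y = factor(.data$rlu_max), fill = .data$rate
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "max p-value", y = "max mean RLU", fill = "validation\nrate") +
    ggplot2::theme_minimal()
}

#' Plot a predictor benchmark
#'
#' Specificity against sensitivity for every (tool, stringency) tier, point
#' size encoding balanced accuracy.
#'
#' @param metrics tibble from [benchmark_tools()].
#' @return a ggplot object.
#' @export
plot_benchmark <- function(metrics) {
  stopifnot_cols(metrics, c("tool_name", "sensitivity", "specificity", "balanced_accuracy"), "metrics")
  ggplot2::ggplot(metrics, ggplot2::aes(
    x = .data$specificity, y = .data$sensitivity,
    size = .data$balanced_accuracy, label = .data$tool_name
  )) +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::geom_text(size = 2.7, vjust = -1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "specificity", y = "sensitivity", size = "balanced\naccuracy"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.candidate_screen <- function(object, ...) {
  counts <- tibble(
    stage = factor(names(object$stage_counts), levels = names(object$stage_counts)),
    pairs = as.integer(object$stage_counts)
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$stage, y = .data$pairs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$pairs), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "(miRNA, gene) pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.length_bias <- function(object, ...) {
  dat <- tibble(ratio = object$ratios)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 15, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "long / short mean RLU", y = "genes") +
    ggplot2::theme_minimal()
}
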