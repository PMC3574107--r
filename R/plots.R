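#' Plot per-order accuracies of an evaluation report
#'
#' Bar chart of the j-th order prediction accuracies with the `M/L` random
#' baseline as a dashed reference line.
#'
#' @param object A `tox_eval` from [evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tox_eval
#' @export
autoplot.tox_eval <- function(object, ...) {
  ggplot2::ggplot(object$orders,
                  ggplot2::aes(x = factor(.data$order), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$baseline, linetype = "dashed") +
    ggplot2::labs(
      x = "prediction order j", y = "accuracy",
      title = sprintf("%s evaluation (n = %d)", object$mode, object$n),
      subtitle = sprintf("dashed line: random baseline M/L = %.4f",
                         object$baseline)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a category co-occurrence matrix
#'
#' Heatmap of the pairwise overlap ratios (common/union percentages) with
#' the intersection counts printed in the cells.
#'
#' @param object A `tox_overlap` from [cooccurrence_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tox_overlap
#' @export
autoplot.tox_overlap <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$category_a, y = .data$category_b,
                               fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%.1f%%)", .data$n_both, .data$ratio)
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "overlap %") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Category co-occurrence (common / union)") +
    ggplot2::theme_minimal()
}

#' Plot the category score profile of one query compound
#'
#' @param scores A 7-row tibble from [category_scores()].
#' @param compound Optional compound identifier for the title.
#' @return A ggplot object.
#' @export
plot_category_scores <- function(scores, compound = NULL) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$category, y = .data$score)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = NULL, y = "weighted-vote score",
      title = if (is.null(compound)) "Category scores" else
        sprintf("Category scores for %s", compound)
    ) +
    ggplot2::theme_minimal()
}
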