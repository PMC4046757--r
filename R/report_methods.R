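# Broom-style accessors and plots for cross-validation reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.cv_report <- function(x, ...) {
  hdr <- if (is.null(x$scheme)) "confusion-matrix metrics" else
    sprintf("%s cross-validation (k = %s)", x$scheme, x$k)
  cat(sprintf("<cv_report> %s\n", hdr))
  cat(sprintf("  n = %d   overall accuracy Q = %.1f%%\n", x$n,
              x$overall_accuracy))
  print(x$confusion)
  print(as.data.frame(x$per_class), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-class metrics of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with one row per class: `class`, `sensitivity`,
#'   `specificity` (proportions) and `mcc`.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$per_class

#' One-row summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return One-row tibble: `overall_accuracy` (percent), `n`, `scheme`,
#'   `k`, `seed`, `mean_mcc`.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    overall_accuracy = x$overall_accuracy,
    n = x$n,
    scheme = x$scheme %||% NA_character_,
    k = x$k %||% NA_integer_,
    seed = x$seed %||% NA_integer_,
    mean_mcc = mean(x$per_class$mcc))
}

#' Confusion-matrix heatmap of a cross-validation report
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot: true class by predicted class, tiles shaded by count.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("Overall accuracy %.1f%% (n = %d)",
                      object$overall_accuracy, object$n),
      x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Accuracy-by-feature-group plot for an ablation table
#'
#' @param ablation Tibble from [run_ablation()].
#' @return A ggplot of cross-validation accuracy against the cumulative
#'   feature groups.
#' @export
plot_ablation <- function(ablation) {
  ablation$groups <- factor(ablation$groups, levels = ablation$groups)
  ggplot2::ggplot(ablation,
                  ggplot2::aes(x = .data$groups, y = .data$accuracy,
                               group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cumulative feature groups",
                  y = "10-fold CV accuracy (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
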