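# ggplot2 displays for result objects.

#' Plot per-location success rates of a metrics report
#'
#' Bar chart of the per-location success rates with the overall locative and
#' absolute accuracies drawn as reference lines.
#'
#' @param object An `eccloc_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eccloc_metrics <- function(object, ...) {
  df <- object$per_location
  ggplot2::ggplot(df, ggplot2::aes(x = .data$location, y = .data$success_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overall_locative_accuracy,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$overall_absolute_accuracy,
                        linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "per-location success rate",
                  title = sprintf("Locative %.3f (dashed) / absolute %.3f (dotted), %d proteins",
                                  object$overall_locative_accuracy,
                                  object$overall_absolute_accuracy,
                                  object$n_dif)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a jackknife report
#'
#' @param object An `eccloc_jackknife` object.
#' @param ... Unused.
#' @return A ggplot object (see [autoplot.eccloc_metrics()]).
#' @export
autoplot.eccloc_jackknife <- function(object, ...) {
  autoplot(object$metrics, ...)
}

#' Plot the signed score distribution of a set of predictions
#'
#' Box plots of the per-label ensemble scores, split by whether the label is
#' in the protein's true set — a quick view of label separation.
#'
#' @param predictions A predictions tibble with `truth` and `score_*` columns
#'   (e.g. `jackknife(...)$predictions`).
#' @return A ggplot object.
#' @export
plot_score_separation <- function(predictions) {
  score_cols <- grep("^score_", names(predictions), value = TRUE)
  long <- tidyr::pivot_longer(predictions, dplyr::all_of(score_cols),
                              names_to = "location", values_to = "score",
                              names_prefix = "score_")
  long$carrier <- mapply(function(tr, l) l %in% tr, long$truth, long$location)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$location, y = .data$score,
                                     fill = .data$carrier)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "ensemble decision score", fill = "true label") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
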