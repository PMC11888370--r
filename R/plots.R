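#' Plot the outcome breakdown of a decoding run
#'
#' Bar-chart version of the decoding report's failure-cause pie: one bar
#' per outcome status, as a fraction of all reads.
#'
#' @param object A `decode_run` or `decode_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decode_report <- function(object, ...) {
  d <- tidy.decode_report(if (inherits(object, "decode_run")) object$report else object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$status, -.data$proportion),
                                  y = .data$proportion, fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of reads", fill = "condition",
                  title = "Decoding outcomes") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.decode_report
#' @export
autoplot.decode_run <- function(object, ...) autoplot.decode_report(object$report, ...)

#' Rank plot of an enrichment metric
#'
#' Compounds (or synthons) ordered by a metric, highlighting those above a
#' threshold -- the standard way to eyeball how far the enriched tail
#' stands out of the background.
#'
#' @param table An `enrichment_table` from [compute_enrichment()].
#' @param metric Metric column to plot (default `"zscore"`).
#' @param threshold Optional horizontal reference line.
#' @return A ggplot.
#' @export
plot_enrichment <- function(table, metric = "zscore", threshold = NULL) {
  d <- tibble::as_tibble(table)
  d <- d[order(-d[[metric]]), ]
  d$rank <- seq_len(nrow(d))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data[[metric]])) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "rank", y = metric, title = paste("Enrichment:", metric)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed", colour = "red")
  }
  p
}

#' Bar chart of replicate-overlap region counts
#'
#' @param overlap Output of [replicate_overlap()].
#' @return A ggplot.
#' @export
plot_replicate_overlap <- function(overlap) {
  ggplot2::ggplot(overlap,
                  ggplot2::aes(x = stats::reorder(.data$members, .data$degree),
                               y = .data$n_keys, fill = factor(.data$degree))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "keys passing threshold", fill = "replicates",
                  title = "Replicate reproducibility") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Per-fold accuracy of the baseline classifier vs the dummy
#'
#' @param object An `ml_eval` from [balance_and_evaluate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ml_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(object$folds, c("model_accuracy", "dummy_accuracy"),
                           names_to = "classifier", values_to = "accuracy")
  d$classifier <- sub("_accuracy", "", d$classifier)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy,
                                  colour = .data$classifier, group = .data$classifier)) +
    ggplot2::geom_point(size = 2) + ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fold", y = "accuracy", title = "Baseline model vs dummy") +
    ggplot2::theme_minimal()
}
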