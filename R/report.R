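new_triage_report <- function(calls, method, config) {
  is_s <- calls$label == "suspicious"
  called_s <- calls$call == "suspicious"
  metrics <- confusion_metrics(tp = sum(is_s & called_s),
                               fp = sum(!is_s & called_s),
                               tn = sum(!is_s & !called_s),
                               fn = sum(is_s & !called_s))
  structure(list(calls = calls, metrics = metrics, method = method,
                 config = config),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf("<triage_report> %s on %d images\n", x$method, nrow(x$calls)))
  if (!is.null(x$config$subset)) {
    cat("  features:", paste(x$config$subset, collapse = ", "), "\n")
  }
  m <- x$metrics
  cat(sprintf("  sensitivity %.3f  specificity %.3f  ppv %.3f  npv %.3f  gain %.2f\n",
              m$sensitivity, m$specificity, m$ppv, m$npv, m$prevalence_gain))
  invisible(x)
}

#' Tidy per-image calls of a triage report
#'
#' @param x A `triage_report` from [knn_loocv()] or [nb_report()].
#' @param ... Unused.
#' @return Tibble with one row per image: `source_id`, `label`, `score`,
#'   `call`.
#' @method tidy triage_report
#' @export
tidy.triage_report <- function(x, ...) x$calls

#' One-row performance summary of a triage report
#'
#' @inheritParams tidy.triage_report
#' @return One-row tibble of confusion counts and derived metrics.
#' @method glance triage_report
#' @export
glance.triage_report <- function(x, ...) x$metrics

#' ROC curve plot
#'
#' @param object A `roc_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot: sensitivity against 1 - specificity, with the chance
#'   diagonal.
#' @method autoplot roc_sweep
#' @export
autoplot.roc_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Sensitivity/specificity against neighbour count
#'
#' Companion plot for [knn_search()] results: how the best-subset
#' sensitivity and specificity move as the number of voting neighbours
#' grows.
#'
#' @param search A tibble from [knn_search()].
#' @return A ggplot.
#' @export
plot_knn_sweep <- function(search) {
  long <- tidyr::pivot_longer(search[c("k", "sensitivity", "specificity")],
                              c("sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     linetype = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(sensitivity = "solid",
                                              specificity = "dashed")) +
    ggplot2::labs(x = "Number of neighbours", y = NULL, linetype = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
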