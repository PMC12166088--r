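#' Tidy a recommendation into a per-drug tibble
#'
#' @param x A `recommendation` from [fit_and_rank()].
#' @param ... Unused.
#' @return Tibble with `drug_id`, `rank`, `predicted`, `predicted_hit`,
#'   best-first.
#' @export
tidy.recommendation <- function(x, ...) {
  x$predictions[, c("drug_id", "rank", "predicted", "predicted_hit")]
}

#' @export
glance.recommendation <- function(x, ...) {
  tibble(
    new_cell_id = x$new_cell_id %||% NA_character_,
    n_panel_drugs = length(x$panel_drugs),
    n_predicted = nrow(x$predictions),
    n_predicted_hits = length(x$predicted_hits),
    learner = x$learner,
    n_trees = x$n_trees,
    low_confidence = x$low_confidence
  )
}

#' @export
tidy.evaluation_report <- function(x, ...) x$per_cell

#' @export
glance.evaluation_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
}

#' @export
tidy.loo_report <- function(x, ...) x$per_cell

#' @export
glance.loo_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
}

#' Plot a ranked recommendation
#'
#' Predicted activity against rank, predicted hits highlighted and the hit
#' threshold drawn.
#'
#' @param object A `recommendation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recommendation <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$predicted,
                                   colour = .data$predicted_hit)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_hline(yintercept = object$scheme$hit_threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey40"),
                                 name = "predicted hit") +
    ggplot2::labs(
      x = "rank (best first)",
      y = paste0("predicted activity (", object$scheme$name, ")"),
      title = if (!is.null(object$new_cell_id))
        paste("Drug ranking for", object$new_cell_id) else "Drug ranking"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-cell metric distributions of a hold-out report
#'
#' @param object An `evaluation_report` from [run_holdout()].
#' @param metrics Metric columns to show; defaults to the correlation and
#'   hit-rate metrics.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object,
                                       metrics = c("r_pearson", "r_spearman",
                                                   "hit_rate"), ...) {
  df <- object$per_cell |>
    tidyr::pivot_longer(dplyr::any_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subset, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-cell-line evaluation metrics") +
    ggplot2::theme_minimal()
}

#' Plot the tissue composition of the most influential cell lines
#'
#' @param composition A tibble from [tissue_composition()].
#' @return A ggplot object.
#' @export
plot_tissue_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = stats::reorder(.data$tissue, .data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "cell lines among the most influential",
                  title = "Tissue of origin of influential cell lines") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
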