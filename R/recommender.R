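#' Build the training/prediction table for one new cell line
#'
#' The recommender flips the usual layout: *drugs are the samples and
#' historical cell lines are the features*. Each panel drug contributes one
#' training row — its activities across the historical cell lines — with
#' the new cell line's measured activity for that drug as the target. Every
#' remaining library drug contributes a prediction row with the same
#' feature layout.
#'
#' Only the new cell line's panel measurements are ever read; passing a
#' profile that covers more drugs than the panel is fine, the extras are
#' ignored (and a leakage check rejects a new cell that is itself among the
#' historical cells).
#'
#' @param historical A completed (no missing entries) [response_matrix()]
#'   of historical cell lines by library drugs, on the activity scale.
#' @param panel_drugs Character vector of probing-panel drug ids.
#' @param new_profile The new cell line's measured panel activities: a
#'   named numeric vector or a two-column data frame (`drug_id`, `value`).
#'   Must cover every panel drug.
#' @param historical_cells Optional subset of historical cell ids to use as
#'   features; default all.
#' @param new_cell_id Optional id of the new cell line, used for the
#'   leakage check and carried into downstream results.
#' @return An object of class `recommender_table`: training features/targets
#'   over panel drugs and prediction features over the remaining library.
#' @export
build_training_table <- function(historical, panel_drugs, new_profile,
                                 historical_cells = NULL,
                                 new_cell_id = NULL) {
  if (is.null(historical_cells)) historical_cells <- cell_ids(historical)
  missing_cells <- setdiff(historical_cells, cell_ids(historical))
  if (length(missing_cells) > 0) {
    abort(paste0("Unknown historical cells: ",
                 paste(missing_cells, collapse = ", ")))
  }
  if (!is.null(new_cell_id) && new_cell_id %in% historical_cells) {
    abort(paste0("New cell line '", new_cell_id,
                 "' is among the historical cells: leakage."))
  }
  absent <- setdiff(panel_drugs, drug_ids(historical))
  if (length(absent) > 0) {
    abort(paste0("Panel drugs absent from the historical matrix: ",
                 paste(absent, collapse = ", ")))
  }
  if (anyDuplicated(panel_drugs)) abort("Duplicate panel drugs.")
  if (is.data.frame(new_profile)) {
    prof <- stats::setNames(new_profile[[2]], as.character(new_profile[[1]]))
  } else {
    prof <- new_profile
  }
  uncovered <- setdiff(panel_drugs, names(prof))
  if (length(uncovered) > 0) {
    abort(paste0("New profile does not cover panel drugs: ",
                 paste(uncovered, collapse = ", ")))
  }
  targets <- prof[panel_drugs]
  if (anyNA(targets)) abort("Panel measurements of the new cell must be non-missing.")
  H <- historical$values[historical_cells, , drop = FALSE]
  if (anyNA(H)) {
    abort("Historical matrix has missing entries over the selected cells; impute first.")
  }
  library_drugs <- setdiff(drug_ids(historical), panel_drugs)
  if (length(panel_drugs) == 1) {
    warn("Single-drug panel: the model will be fitted on one training row.")
  }
  structure(
    list(
      x_train = t(H[, panel_drugs, drop = FALSE]),
      y_train = targets,
      x_predict = t(H[, library_drugs, drop = FALSE]),
      panel_drugs = panel_drugs,
      library_drugs = library_drugs,
      historical_cells = historical_cells,
      new_cell_id = new_cell_id,
      scheme = historical$scheme
    ),
    class = "recommender_table"
  )
}

#' @export
print.recommender_table <- function(x, ...) {
  cat("<recommender_table> ", length(x$panel_drugs), " panel drugs x ",
      length(x$historical_cells), " historical cell lines; ",
      length(x$library_drugs), " library drugs to predict\n", sep = "")
  invisible(x)
}

#' Fit the recommender and rank the drug library
#'
#' Fits a tree-ensemble regressor (random forest with 50 trees and library
#' defaults, or gradient boosting) on the panel rows of a
#' [build_training_table()] result, predicts the activity of every
#' remaining library drug, ranks them best-first under the scheme's ranking
#' direction (ties broken by drug id), flags predicted hits with the same
#' threshold as measured hits, and extracts normalised per-cell-line
#' feature importances.
#'
#' @param table A `recommender_table`.
#' @param learner `"random_forest"` (default) or `"gradient_boosting"`.
#' @param n_trees Ensemble size; default 50.
#' @param seed Integer seed for the ensemble's randomness.
#' @return An object of class `recommendation` with elements
#'   `predictions` (tibble: `drug_id`, `predicted`, `rank`,
#'   `predicted_hit`, best-first), `ranking`, `predicted_hits`,
#'   `importances` (tibble: `cell_id`, `importance`, summing to 1 when
#'   defined), `new_cell_id`, `low_confidence` (constant training target)
#'   and the learner settings.
#' @export
fit_and_rank <- function(table, learner = c("random_forest",
                                            "gradient_boosting"),
                         n_trees = 50, seed = 1) {
  learner <- match.arg(learner)
  stopifnot(inherits(table, "recommender_table"), n_trees >= 1)
  y <- table$y_train
  if (!all(is.finite(table$x_train)) || !all(is.finite(y))) {
    abort("Training table must be finite.")
  }
  low_confidence <- var(y) == 0
  if (learner == "random_forest") {
    fit <- withr::with_seed(as.integer(seed),
      randomForest::randomForest(x = table$x_train, y = y, ntree = n_trees))
    pred <- as.numeric(predict(fit, table$x_predict))
    imp <- fit$importance[, 1]
  } else {
    booster <- withr::with_seed(as.integer(seed),
      xgboost::xgb.train(
        params = list(max_depth = 3, eta = 0.1, lambda = 0,
                      objective = "reg:squarederror",
                      base_score = mean(y), nthread = 1,
                      seed = as.integer(seed)),
        data = xgboost::xgb.DMatrix(table$x_train, label = y),
        nrounds = n_trees, verbose = 0))
    pred <- as.numeric(predict(booster, xgboost::xgb.DMatrix(table$x_predict)))
    gain <- xgboost::xgb.importance(model = booster)
    imp <- stats::setNames(rep(0, length(table$historical_cells)),
                           table$historical_cells)
    if (!is.null(gain) && nrow(gain) > 0) imp[gain$Feature] <- gain$Gain
  }
  names(pred) <- table$library_drugs
  total <- sum(imp)
  importance <- if (total > 0) imp / total else rep(NA_real_, length(imp))
  ranking <- rank_drug_ids(pred, table$scheme)
  predictions <- tibble(
    drug_id = ranking,
    predicted = unname(pred[ranking]),
    rank = seq_along(ranking),
    predicted_hit = unname(is_hit(pred[ranking], table$scheme))
  )
  structure(
    list(
      new_cell_id = table$new_cell_id,
      predictions = predictions,
      ranking = ranking,
      predicted_hits = predictions$drug_id[predictions$predicted_hit],
      importances = tibble(cell_id = table$historical_cells,
                           importance = unname(importance)),
      panel_drugs = table$panel_drugs,
      scheme = table$scheme,
      learner = learner, n_trees = n_trees, seed = seed,
      low_confidence = low_confidence
    ),
    class = "recommendation"
  )
}

#' One-call recommendation for a new cell line
#'
#' Convenience wrapper: [build_training_table()] then [fit_and_rank()].
#'
#' @inheritParams build_training_table
#' @inheritParams fit_and_rank
#' @return A `recommendation`; see [fit_and_rank()].
#' @export
recommend_drugs <- function(historical, panel_drugs, new_profile,
                            historical_cells = NULL, new_cell_id = NULL,
                            learner = "random_forest", n_trees = 50,
                            seed = 1) {
  tbl <- build_training_table(historical, panel_drugs, new_profile,
                              historical_cells, new_cell_id)
  fit_and_rank(tbl, learner = learner, n_trees = n_trees, seed = seed)
}

#' @export
print.recommendation <- function(x, ...) {
  cat("<recommendation>",
      if (!is.null(x$new_cell_id)) paste0(" for '", x$new_cell_id, "'"),
      ": ", length(x$ranking), " drugs ranked, ",
      length(x$predicted_hits), " predicted hits (", x$learner, ", ",
      x$n_trees, " trees)\n", sep = "")
  if (x$low_confidence) cat("  low confidence: constant training target\n")
  print(head(x$predictions, 5))
  invisible(x)
}

#' Tissue composition of the most influential cell lines
#'
#' Ranks historical cell lines by feature importance and tabulates the
#' tissues of origin among the top `top_k` — the view used to ask whether
#' prediction leans on same-tissue cell lines. Cells without an annotation
#' are counted as `"unknown"`.
#'
#' @param x A `recommendation` or an importances tibble
#'   (`cell_id`, `importance`).
#' @param annotations Data frame with columns `cell_id` and `tissue`.
#' @param top_k Number of top cell lines to tabulate; default 10.
#' @return A tibble (`tissue`, `n`), `n` summing to `top_k`, most frequent
#'   first.
#' @export
tissue_composition <- function(x, annotations, top_k = 10) {
  imp <- if (inherits(x, "recommendation")) x$importances else as_tibble(x)
  stopifnot(all(c("cell_id", "importance") %in% names(imp)),
            all(c("cell_id", "tissue") %in% names(annotations)),
            top_k <= nrow(imp))
  top <- imp |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$cell_id) |>
    head(top_k) |>
    dplyr::left_join(as_tibble(annotations)[, c("cell_id", "tissue")],
                     by = "cell_id") |>
    dplyr::mutate(tissue = dplyr::coalesce(.data$tissue, "unknown"))
  top |>
    dplyr::count(.data$tissue, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$tissue)
}
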