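#' Split cell lines into training / validation / test sets
#'
#' Random, disjoint, exhaustive partition of the cell lines with
#' largest-remainder rounding of the split sizes (so an 809-cell screen
#' under 80/10/10 yields 647/81/81).
#'
#' @param m A [response_matrix()] or a character vector of cell ids.
#' @param fractions Numeric length-3 vector summing to 1; default
#'   `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed.
#' @return Named list of character vectors: `train`, `validation`, `test`.
#' @export
split_dataset <- function(m, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  ids <- if (inherits(m, "response_matrix")) cell_ids(m) else m
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  n <- length(ids)
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac_part <- fractions * n - sizes
    bump <- order(-frac_part)[seq_len(rem)]
    sizes[bump] <- sizes[bump] + 1
  }
  if (any(sizes == 0)) {
    abort("Split produced an empty set; use more cell lines.")
  }
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  list(
    train = shuffled[seq_len(sizes[1])],
    validation = shuffled[sizes[1] + seq_len(sizes[2])],
    test = shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])]
  )
}

#' Configuration of a repeated hold-out experiment
#'
#' Bundles every knob of the hold-out protocol: the 80/10/10 split, the
#' number of repeated experiments, the probing-panel size and selection
#' method, the historical cohort size, the imputation method, and the
#' learner.
#'
#' @param n_repeats Number of independent experiments; default 5.
#' @param split_fractions Train/validation/test fractions; default
#'   `c(0.8, 0.1, 0.1)`.
#' @param panel_size Probing-panel size; default 30.
#' @param panel_method `"diversity"` (correlation-diversity algorithm,
#'   default) or `"random"`.
#' @param n_historical_cells Historical cohort size per model; default 100.
#' @param imputation `"tml"` (default) or `"zero"`.
#' @param learner,n_trees Passed to [fit_and_rank()].
#' @param top_n,hit_k Passed to [evaluate_recommendation()].
#' @param seed_base Base seed; repeat `r` uses `seed_base + r - 1` for
#'   every random draw (split, panel, cohort, forest).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_repeats = 5,
                              split_fractions = c(0.8, 0.1, 0.1),
                              panel_size = 30,
                              panel_method = c("diversity", "random"),
                              n_historical_cells = 100,
                              imputation = c("tml", "zero"),
                              learner = "random_forest", n_trees = 50,
                              top_n = c(10, 20, 30), hit_k = 10,
                              seed_base = 1) {
  stopifnot(n_repeats >= 1, panel_size >= 1, n_historical_cells >= 1)
  structure(
    list(n_repeats = n_repeats, split_fractions = split_fractions,
         panel_size = panel_size, panel_method = match.arg(panel_method),
         n_historical_cells = n_historical_cells,
         imputation = match.arg(imputation), learner = learner,
         n_trees = n_trees, top_n = top_n, hit_k = hit_k,
         seed_base = as.integer(seed_base)),
    class = "experiment_config"
  )
}

#' Repeated hold-out evaluation of the recommender
#'
#' Runs the full protocol `n_repeats` times: split the cell lines 80/10/10,
#' impute the training cells (validation and test cells excluded from
#' imputation and panel selection), select the probing panel and the
#' historical cohort on the training set, then for every test cell line
#' recommend from its panel measurements alone and score the predictions
#' on its remaining measured drugs — over all drugs and over the selective
#' subset. Per-metric means are taken over the test cells of each repeat,
#' then summarised as mean/sd across repeats.
#'
#' A test cell missing a panel-drug measurement has that drug dropped from
#' its personal panel (with a warning at the repeat level).
#'
#' @param m A pruned, transformed [response_matrix()].
#' @param config An [experiment_config()].
#' @return A list of class `evaluation_report`: `per_cell` (tibble of
#'   per-cell, per-subset metrics with `experiment` and `cell_id`
#'   columns), `summary` (mean/sd across repeats of the per-repeat mean of
#'   every metric; hit metrics additionally restricted to evaluable
#'   cells), `panels` (drug panel per repeat), and `config`.
#' @export
run_holdout <- function(m, config = experiment_config()) {
  if (!m$transformed) abort("Transform the matrix before running.")
  per_cell <- vector("list", config$n_repeats)
  panels <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    seed_r <- config$seed_base + r - 1L
    split <- split_dataset(m, config$split_fractions, seed = seed_r)
    holdout <- c(split$validation, split$test)
    train_m <- m[split$train, ]
    completed <- switch(config$imputation,
      zero = impute_zero(train_m),
      tml = impute_tml(train_m, seed = seed_r)
    )
    sel_mask <- selective_drugs(call_hits(train_m))
    panel <- if (config$panel_method == "diversity") {
      fit_panel_to_size(train_m, "drugs", target_size = config$panel_size)
    } else {
      select_random(train_m, "drugs", config$panel_size, seed = seed_r)
    }
    panels[[r]] <- panel
    hist_cells <- select_random(train_m, "cells",
                                min(config$n_historical_cells,
                                    length(split$train)),
                                seed = seed_r)
    n_dropped <- 0L
    rows <- purrr::map(split$test, function(cid) {
      measured <- m$values[cid, ]
      cell_panel <- panel[!is.na(measured[panel])]
      n_dropped <<- n_dropped + (length(panel) - length(cell_panel))
      if (length(cell_panel) < 2) return(NULL)
      rec <- recommend_drugs(
        completed, cell_panel, measured[cell_panel],
        historical_cells = hist_cells, new_cell_id = cid,
        learner = config$learner, n_trees = config$n_trees,
        seed = derive_seed(seed_r, cid)
      )
      actual <- measured[setdiff(drug_ids(m), cell_panel)]
      evaluate_recommendation(rec, actual, selective = sel_mask,
                              top_n = config$top_n,
                              hit_k = config$hit_k) |>
        dplyr::mutate(experiment = r, cell_id = cid, .before = 1)
    })
    if (n_dropped > 0) {
      warn(paste0("Experiment ", r, ": dropped ", n_dropped,
                  " unmeasured panel entries across test cells."))
    }
    per_cell[[r]] <- dplyr::bind_rows(rows)
  }
  per_cell <- dplyr::bind_rows(per_cell)
  structure(
    list(per_cell = per_cell,
         summary = summarise_experiments(per_cell),
         panels = panels, config = config),
    class = "evaluation_report"
  )
}

# per-repeat means per subset, then mean/sd across repeats
summarise_experiments <- function(per_cell) {
  metric_cols <- setdiff(
    names(per_cell)[vapply(per_cell, is.numeric, logical(1))],
    c("experiment", "n_drugs")
  )
  per_repeat <- per_cell |>
    dplyr::group_by(.data$subset, .data$experiment) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE)),
      n_hits_topk_evaluable = mean(.data$n_hits_topk[which(.data$evaluable)]),
      hit_rate_evaluable = mean(.data$hit_rate[which(.data$evaluable)]),
      n_cells = dplyr::n(), n_evaluable = sum(.data$evaluable, na.rm = TRUE),
      .groups = "drop"
    )
  per_repeat |>
    tidyr::pivot_longer(-c("subset", "experiment"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$subset, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$config$n_repeats, " experiment(s), ",
      length(unique(x$per_cell$cell_id)), " test cell lines\n", sep = "")
  key <- x$summary[x$summary$metric %in%
                     c("r_pearson", "r_spearman", "rmse", "hit_rate"), ]
  print(key, n = nrow(key))
  invisible(x)
}

#' Leave-one-out protocol for small, near-complete screens
#'
#' The design for a small panel screened directly on patient biopsies:
#' for each cell line in turn, every measured drug is predicted from the
#' cell line's responses to its *other* measured drugs (the panel) and the
#' profiles of all other cell lines (imputed without looking at the
#' held-out line). The per-drug predictions are assembled into a full
#' predicted profile, from which the report draws: Spearman correlation
#' with the measured profile, mean measured viability of the whole library
#' and of the `top_k` best-predicted drugs, and the number of hits
#' available / predicted / identified. Cell lines with no hits available
#' are flagged non-evaluable for the hit analysis; cell lines with fewer
#' than 3 measured drugs are skipped with a warning.
#'
#' @param m A pruned [response_matrix()] on the activity scale (typically
#'   viability).
#' @param n_repeats Number of repeated experiments (re-seeding the
#'   ensembles); default 5.
#' @param imputation `"tml"` (default) or `"zero"` for completing the
#'   historical matrix.
#' @param learner,n_trees Passed to [fit_and_rank()].
#' @param top_k Depth of the "top ranked" viability summary; default 5.
#' @param seed_base Base seed; repeat `r` uses `seed_base + r - 1`.
#' @return A list of class `loo_report`: `per_cell` (tibble with one row
#'   per cell line and repeat), `summary` (mean/sd across repeats of
#'   per-repeat means), and the settings.
#' @export
run_leave_one_out <- function(m, n_repeats = 5,
                              imputation = c("tml", "zero"),
                              learner = "random_forest", n_trees = 50,
                              top_k = 5, seed_base = 1) {
  imputation <- match.arg(imputation)
  if (!m$transformed) abort("Transform the matrix before running.")
  cells <- cell_ids(m)
  rows <- list()
  for (r in seq_len(n_repeats)) {
    seed_r <- as.integer(seed_base) + r - 1L
    for (cid in cells) {
      measured <- m$values[cid, ]
      measured <- measured[!is.na(measured)]
      if (length(measured) < 3) {
        warn(paste0("Cell '", cid, "' has fewer than 3 measured drugs; skipped."))
        next
      }
      hist_m <- m[setdiff(cells, cid), ]
      completed <- switch(imputation,
        zero = impute_zero(hist_m),
        tml = impute_tml(hist_m, seed = derive_seed(seed_r, cid))
      )
      pred <- purrr::map_dbl(names(measured), function(d) {
        cell_panel <- setdiff(names(measured), d)
        rec <- recommend_drugs(
          completed[, c(cell_panel, d)], cell_panel, measured[cell_panel],
          new_cell_id = cid, learner = learner, n_trees = n_trees,
          seed = derive_seed(seed_r, paste0(cid, "::", d))
        )
        rec$predictions$predicted[rec$predictions$drug_id == d]
      })
      names(pred) <- names(measured)
      ranking <- rank_drug_ids(pred, m$scheme)
      hits_avail <- is_hit(measured, m$scheme)
      hits_pred <- is_hit(pred, m$scheme)
      identified <- sum(hits_avail & hits_pred)
      top_ids <- head(ranking, top_k)
      rows[[length(rows) + 1]] <- tibble(
        experiment = r, cell_id = cid, n_drugs = length(measured),
        r_spearman = suppressWarnings(
          cor(pred, measured, method = "spearman")),
        library_activity = mean(measured),
        topk_activity = mean(measured[top_ids]),
        n_hits_available = sum(hits_avail),
        n_hits_predicted = sum(hits_pred),
        n_hits_identified = identified,
        hit_rate = if (sum(hits_pred) > 0) identified / sum(hits_pred) else 0,
        frac_hits_found = if (sum(hits_avail) > 0)
          identified / sum(hits_avail) else NA_real_,
        evaluable = sum(hits_avail) > 0
      )
    }
  }
  per_cell <- dplyr::bind_rows(rows)
  summary <- per_cell |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(
      r_spearman = mean(.data$r_spearman),
      library_activity = mean(.data$library_activity),
      topk_activity = mean(.data$topk_activity),
      n_hits_available = mean(.data$n_hits_available),
      n_hits_predicted = mean(.data$n_hits_predicted),
      n_hits_identified = mean(.data$n_hits_identified),
      hit_rate = mean(.data$hit_rate[.data$evaluable]),
      frac_hits_found = mean(.data$frac_hits_found[.data$evaluable]),
      n_drugs = mean(.data$n_drugs),
      n_evaluable = sum(.data$evaluable),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"experiment", names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(
    list(per_cell = per_cell, summary = summary,
         settings = list(n_repeats = n_repeats, imputation = imputation,
                         learner = learner, n_trees = n_trees,
                         top_k = top_k, seed_base = seed_base)),
    class = "loo_report"
  )
}

#' @export
print.loo_report <- function(x, ...) {
  cat("<loo_report> ", length(unique(x$per_cell$cell_id)), " cell lines, ",
      x$settings$n_repeats, " repeat(s)\n", sep = "")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}
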