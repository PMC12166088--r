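#' Top-n overlap between predicted and actual drug rankings
#'
#' Set overlap of the two top-n sets divided by n, agnostic to positions
#' within the top n: if 7 of the 10 best-predicted drugs are among the 10
#' actually best drugs, the overlap is 0.7.
#'
#' @param predicted_ranking,actual_ranking Character vectors of the same
#'   drug set, best first.
#' @param n Depth of the comparison; must not exceed the ranking length.
#' @return A fraction in `[0, 1]`.
#' @export
topn_overlap <- function(predicted_ranking, actual_ranking, n) {
  if (!setequal(predicted_ranking, actual_ranking)) {
    abort("The two rankings must cover the same drug set.")
  }
  if (n > length(predicted_ranking)) {
    abort("`n` exceeds the number of evaluable drugs.")
  }
  length(intersect(head(predicted_ranking, n), head(actual_ranking, n))) / n
}

#' True hits among the top-k predicted drugs
#'
#' Counts how many of the k best-predicted drugs are measured hits, and
#' reports the count as a rate over k and as a fraction of the theoretical
#' maximum `min(k, hits available)` — the headroom-adjusted view needed
#' when a cell line has very few hits at all. A cell line with no hits
#' available is flagged non-evaluable.
#'
#' @param predicted_ranking Character vector of drugs, best-predicted first.
#' @param hits Named logical vector of measured hit calls over the same
#'   drugs (`NA` measurements are dropped).
#' @param k Depth; default 10.
#' @return One-row tibble: `k`, `n_hits_topk`, `hit_rate` (`/k`),
#'   `n_hits_available`, `max_possible`, `frac_of_max`, `evaluable`.
#' @export
hit_rate_topk <- function(predicted_ranking, hits, k = 10) {
  hits <- hits[!is.na(hits)]
  predicted_ranking <- predicted_ranking[predicted_ranking %in% names(hits)]
  k <- min(k, length(predicted_ranking))
  n_avail <- sum(hits)
  count <- sum(hits[head(predicted_ranking, k)])
  max_possible <- min(k, n_avail)
  tibble(
    k = k,
    n_hits_topk = as.integer(count),
    hit_rate = if (k > 0) count / k else NA_real_,
    n_hits_available = as.integer(n_avail),
    max_possible = as.integer(max_possible),
    frac_of_max = if (max_possible > 0) count / max_possible else NA_real_,
    evaluable = n_avail > 0
  )
}

#' Pearson/Spearman correlation and RMSE of paired activities
#'
#' @param predicted,actual Numeric vectors; pairs with a missing value on
#'   either side are dropped. At least 3 complete pairs are required.
#' @return One-row tibble: `r_pearson`, `r_spearman`, `rmse`, `n`. A
#'   zero-variance side yields `NA` correlations.
#' @export
regression_metrics <- function(predicted, actual) {
  ok <- !is.na(predicted) & !is.na(actual)
  p <- predicted[ok]; a <- actual[ok]
  if (length(p) < 3) abort("Need at least 3 paired non-missing values.")
  degenerate <- sd(p) == 0 || sd(a) == 0
  tibble(
    r_pearson = if (degenerate) NA_real_ else cor(p, a),
    r_spearman = if (degenerate) NA_real_ else
      cor(p, a, method = "spearman"),
    rmse = sqrt(mean((p - a)^2)),
    n = length(p)
  )
}

#' Evaluate a recommendation against measured responses
#'
#' Computes the full metric battery for one cell line — correlations and
#' RMSE of predicted vs measured activity, top-n overlaps, and the top-k
#' hit rate — on the non-panel drugs with a measured response, both over
#' all drugs and (when `selective` is given) restricted to the selective
#' subset. The actual ranking uses the same ranking direction and
#' id-lexicographic tie-break as the predictions.
#'
#' @param result A `recommendation` from [fit_and_rank()].
#' @param actual Named numeric vector of the cell line's measured
#'   activities over library drugs (`NA` allowed; panel drugs are ignored).
#' @param selective Optional named logical vector from [selective_drugs()]
#'   (computed on training reference data).
#' @param top_n Depths for [topn_overlap()]; default `c(10, 20, 30)`. A
#'   depth exceeding the evaluable drug count yields `NA`.
#' @param hit_k Depth for [hit_rate_topk()]; default 10.
#' @return A tibble with one row per subset (`all_drugs`, and
#'   `selective_drugs` when requested) holding the metrics plus the
#'   subset's baseline hit prevalence.
#' @export
evaluate_recommendation <- function(result, actual, selective = NULL,
                                    top_n = c(10, 20, 30), hit_k = 10) {
  stopifnot(inherits(result, "recommendation"))
  scheme <- result$scheme
  eval_one <- function(drug_set, label) {
    act <- actual[names(actual) %in% drug_set]
    act <- act[!is.na(act)]
    if (length(act) < 3) {
      return(tibble(subset = label, n_drugs = length(act)))
    }
    pred <- result$predictions
    pred <- pred[pred$drug_id %in% names(act), ]
    pred_rank <- pred$drug_id
    act_rank <- rank_drug_ids(act, scheme)
    hits <- is_hit(act, scheme)
    pv <- stats::setNames(pred$predicted, pred$drug_id)
    metr <- regression_metrics(pv[names(act)], act)
    overlaps <- purrr::map_dbl(top_n, function(n) {
      if (n > length(act)) NA_real_ else topn_overlap(pred_rank, act_rank, n)
    })
    names(overlaps) <- paste0("top_", top_n)
    hr <- hit_rate_topk(pred_rank, hits, hit_k)
    dplyr::bind_cols(
      tibble(subset = label, n_drugs = length(act)),
      metr[, c("r_pearson", "r_spearman", "rmse")],
      as_tibble(as.list(overlaps)),
      hr[, c("n_hits_topk", "hit_rate", "n_hits_available",
             "max_possible", "frac_of_max", "evaluable")],
      tibble(baseline_prevalence = mean(hits, na.rm = TRUE))
    )
  }
  library_drugs <- result$predictions$drug_id
  out <- eval_one(library_drugs, "all_drugs")
  if (!is.null(selective)) {
    sel_ids <- names(selective)[selective]
    out <- dplyr::bind_rows(out,
                            eval_one(intersect(library_drugs, sel_ids),
                                     "selective_drugs"))
  }
  out
}
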