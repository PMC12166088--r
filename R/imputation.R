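#' Zero-fill imputation
#'
#' Replaces every missing entry with 0 on the activity scale. Observed
#' entries are untouched; the `imputed` flag records which entries were
#' filled.
#'
#' @param m A [response_matrix()] on the activity scale.
#' @return A completed [response_matrix()] with an `imputation` report
#'   attached (see [imputation_report()]).
#' @export
impute_zero <- function(m) {
  vals <- m$values
  filled <- is.na(vals)
  vals[filled] <- 0
  imputed <- m$imputed | filled
  out <- response_matrix(vals, m$scheme, transformed = m$transformed,
                         imputed = imputed)
  n_filled <- colSums(filled)
  attr(out, "imputation") <- tibble(
    drug_id = colnames(vals),
    n_imputed = as.integer(n_filled),
    method = ifelse(n_filled > 0, "zero", "none")
  )
  out
}

#' Transformational-machine-learning (TML) imputation
#'
#' Completes missing entries drug by drug with boosted regression stumps
#' (gradient boosting, 50 rounds, depth 1), using the cell line's responses
#' to the *other* drugs as features — the TML idea of measured bioactivities
#' standing in for structural descriptors. For each drug with missing
#' entries, the feature set is every other drug with fewer than
#' `feature_missing_max` missing entries among eligible cells (those feature
#' gaps are zero-filled), the training samples are the eligible cells where
#' the drug was measured, and the fitted model predicts the drug for the
#' cells where it is missing. Each drug is imputed independently from the
#' original matrix; freshly imputed columns are never chained. Held-out
#' (validation/test) cell lines listed in `exclude_cells` are never read and
#' their entries are left as they are.
#'
#' A drug with no observed values, or with no eligible feature drugs, falls
#' back to zero-fill with a warning.
#'
#' @param m A pruned, transformed [response_matrix()].
#' @param exclude_cells Cell ids (validation + test) excluded from
#'   imputation; their rows are neither used for training nor filled.
#' @param feature_missing_max Absolute missing-entry count below which
#'   another drug qualifies as a feature; default 20.
#' @param n_rounds,learning_rate Boosting rounds and shrinkage; defaults 50
#'   and 0.1.
#' @param seed Integer seed. Each drug's model is seeded from
#'   `(seed, drug_id)` so column order cannot change results.
#' @return A [response_matrix()] with no missing entries among eligible
#'   cells, plus an `imputation` report (see [imputation_report()]).
#' @export
impute_tml <- function(m, exclude_cells = character(),
                       feature_missing_max = 20, n_rounds = 50,
                       learning_rate = 0.1, seed = 1) {
  if (!m$transformed) abort("Transform the matrix before imputing.")
  stopifnot(n_rounds >= 1)
  cells <- cell_ids(m)
  unknown <- setdiff(exclude_cells, cells)
  if (length(unknown) > 0) {
    abort(paste0("Unknown excluded cell ids: ",
                 paste(unknown, collapse = ", ")))
  }
  eligible <- setdiff(cells, exclude_cells)
  if (length(eligible) == 0) abort("No eligible cells left for imputation.")
  E <- m$values[eligible, , drop = FALSE]
  drugs <- colnames(E)
  miss_count <- colSums(is.na(E))

  vals <- m$values
  imputed <- m$imputed
  report <- vector("list", length(drugs))
  for (j in seq_along(drugs)) {
    d <- drugs[j]
    if (miss_count[j] == 0) {
      report[[j]] <- tibble(drug_id = d, n_imputed = 0L, n_features = NA_integer_,
                            method = "none")
      next
    }
    target <- E[, j]
    obs <- !is.na(target)
    # lexicographic feature order so input column order cannot steer
    # split tie-breaking inside the booster
    feats <- sort(drugs[drugs != d & miss_count < feature_missing_max])
    if (!any(obs) || length(feats) == 0) {
      warn(paste0("Drug '", d, "' cannot be TML-modelled (",
                  if (!any(obs)) "no observed values" else "no eligible feature drugs",
                  "); falling back to zero-fill."))
      fill_rows <- eligible[is.na(E[, j])]
      vals[fill_rows, d] <- 0
      imputed[fill_rows, d] <- TRUE
      report[[j]] <- tibble(drug_id = d, n_imputed = length(fill_rows),
                            n_features = 0L, method = "zero_fallback")
      next
    }
    X <- E[, feats, drop = FALSE]
    X[is.na(X)] <- 0
    drug_seed <- derive_seed(seed, d)
    pred <- withr::with_seed(drug_seed, {
      booster <- xgboost::xgb.train(
        params = list(max_depth = 1, eta = learning_rate, lambda = 0,
                      objective = "reg:squarederror",
                      base_score = mean(target[obs]),
                      nthread = 1, seed = drug_seed),
        data = xgboost::xgb.DMatrix(X[obs, , drop = FALSE],
                                    label = target[obs]),
        nrounds = n_rounds, verbose = 0
      )
      predict(booster, xgboost::xgb.DMatrix(X[!obs, , drop = FALSE]))
    })
    fill_rows <- eligible[!obs]
    vals[fill_rows, d] <- pred
    imputed[fill_rows, d] <- TRUE
    report[[j]] <- tibble(drug_id = d, n_imputed = sum(!obs),
                          n_features = length(feats), method = "tml")
  }
  if (m$scheme$name == "viability_percent") vals[vals < 0] <- 0
  out <- response_matrix(vals, m$scheme, transformed = TRUE, imputed = imputed)
  attr(out, "imputation") <- dplyr::bind_rows(report)
  out
}

#' Imputation report of a completed matrix
#'
#' @param m A matrix returned by [impute_zero()] or [impute_tml()].
#' @return A tibble with per-drug imputation counts and the method used
#'   (`"tml"`, `"zero"`, `"zero_fallback"` or `"none"`), or `NULL` if `m`
#'   was not produced by an imputation function.
#' @export
imputation_report <- function(m) attr(m, "imputation")

# deterministic 31-bit seed from a base seed and a string id
derive_seed <- function(seed, id) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(id)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}
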