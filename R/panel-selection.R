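#' Correlation-diversity selection of cell lines or drugs
#'
#' Greedy low-redundancy selection used to build probing panels (over
#' drugs) or historical cohorts (over cell lines):
#'
#' 1. drop the lowest-variance entities, keeping the top
#'    `variance_keep_fraction` by response variance (non-missing entries);
#' 2. compute the Pearson correlation matrix across survivors using
#'    pairwise-complete observations;
#' 3. rank survivors by their median correlation with the others,
#'    ascending;
#' 4. take the lowest-median entity as a reference and exclude every entity
#'    whose correlation with it reaches `correlation_threshold`;
#' 5. move to the next not-yet-excluded entity in the original ranking and
#'    repeat until none remain.
#'
#' The references themselves, in processing order, are the selected diverse
#' panel. Ties in variance and median correlation are broken by
#' lexicographic id; correlations that are undefined (a zero-variance side)
#' or supported by fewer than 3 common observations are treated as 0.
#'
#' @param m A [response_matrix()].
#' @param axis `"drugs"` or `"cells"`: which axis to select over.
#' @param correlation_threshold Number in `(0, 1]`; entities correlating at
#'   or above it with a chosen reference are excluded.
#' @param variance_keep_fraction Fraction of entities kept after the
#'   variance filter; default 0.5 (drop the lowest-variance half).
#' @return Character vector of selected ids, in processing order.
#' @export
select_diverse <- function(m, axis = c("drugs", "cells"),
                           correlation_threshold,
                           variance_keep_fraction = 0.5) {
  axis <- match.arg(axis)
  stopifnot(correlation_threshold > 0, correlation_threshold <= 1,
            variance_keep_fraction > 0, variance_keep_fraction <= 1)
  X <- entity_matrix(m, axis)
  surv <- variance_survivors(X, variance_keep_fraction)
  X <- X[, surv, drop = FALSE]
  C <- robust_pairwise_cor(X)
  med <- if (ncol(C) == 1) 0 else
    vapply(seq_len(ncol(C)), function(j) median(C[-j, j]), numeric(1))
  ranking <- surv[order(med, surv)]
  excluded <- character()
  selected <- character()
  for (e in ranking) {
    if (e %in% excluded) next
    selected <- c(selected, e)
    r_with_e <- C[e, ]
    hits <- names(r_with_e)[r_with_e >= correlation_threshold]
    excluded <- union(excluded, setdiff(hits, e))
  }
  if (length(selected) == 1 && length(ranking) > 1) {
    warn("Correlation threshold left only one entity selected.")
  }
  selected
}

# entities as columns: drugs -> the matrix itself, cells -> its transpose
entity_matrix <- function(m, axis) {
  if (axis == "drugs") m$values else t(m$values)
}

variance_survivors <- function(X, keep_fraction) {
  n_obs <- colSums(!is.na(X))
  if (any(n_obs < 2)) {
    abort("Every entity needs at least 2 non-missing values.")
  }
  v <- apply(X, 2, var, na.rm = TRUE)
  ids <- colnames(X)
  n_keep <- max(1L, ceiling(keep_fraction * length(ids)))
  ids[order(-v, ids)][seq_len(n_keep)]
}

# pairwise-complete Pearson correlations; undefined or thinly supported
# (< 3 common observations) pairs are set to 0
robust_pairwise_cor <- function(X) {
  C <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  n_common <- crossprod(!is.na(X))
  C[n_common < 3] <- 0
  C[is.na(C)] <- 0
  diag(C) <- 1
  C
}

#' Uniform random selection of cell lines or drugs
#'
#' @param m A [response_matrix()].
#' @param axis `"cells"` or `"drugs"`.
#' @param n Number of entities to draw (without replacement).
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return Character vector of `n` unique ids.
#' @export
select_random <- function(m, axis = c("cells", "drugs"), n, seed = 1) {
  axis <- match.arg(axis)
  ids <- if (axis == "cells") cell_ids(m) else drug_ids(m)
  if (n > length(ids)) {
    abort(paste0("Cannot sample ", n, " from ", length(ids), " ", axis, "."))
  }
  withr::with_seed(as.integer(seed), sample(ids, n))
}

#' Fit a diversity panel to a target size
#'
#' The diversity algorithm is controlled by a correlation threshold, not a
#' size; this helper bisects the threshold until [select_diverse()] returns
#' at least `target_size` entities, then truncates the selection in
#' processing order to exactly `target_size`. When duplicated entities make
#' the target unreachable even at threshold 1, the maximum achievable
#' selection is returned with a warning.
#'
#' @inheritParams select_diverse
#' @param target_size Desired panel size; must not exceed the
#'   variance-surviving entity count.
#' @param max_iter Bisection iterations; default 40.
#' @return Character vector of ids, length `target_size` when reachable.
#' @export
fit_panel_to_size <- function(m, axis = c("drugs", "cells"), target_size,
                              variance_keep_fraction = 0.5, max_iter = 40) {
  axis <- match.arg(axis)
  n_surv <- length(variance_survivors(entity_matrix(m, axis),
                                      variance_keep_fraction))
  if (target_size > n_surv) {
    abort(paste0("target_size (", target_size,
                 ") exceeds the variance-surviving count (", n_surv, ")."))
  }
  sel_at <- function(thr) select_diverse(m, axis, thr, variance_keep_fraction)
  best <- suppressWarnings(sel_at(1))
  if (length(best) < target_size) {
    warn(paste0("Only ", length(best), " distinct entities reachable; ",
                "returning the maximum achievable panel."))
    return(best)
  }
  lo <- 0; hi <- 1
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (mid <= 0) break
    cand <- suppressWarnings(sel_at(mid))
    if (length(cand) >= target_size) {
      hi <- mid
      best <- cand
    } else {
      lo <- mid
    }
  }
  head(best, target_size)
}
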