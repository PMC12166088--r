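#' Read a drug-response matrix from delimited text
#'
#' Reads a CSV or TSV (by extension) with one header row and one identifier
#' column, and orients it to the package's internal convention of cell lines
#' as rows and drugs as columns. Empty cells and the sentinels `NA`, `NaN`
#' and `null` (case-insensitive) mark missing measurements. Values are
#' stored untransformed; call [transform_targets()] to move onto the
#' activity scale.
#'
#' @param path Path to a `.csv` (comma) or `.tsv`/`.txt` (tab) file.
#' @param scheme An [activity_scheme()] or scheme name.
#' @param orientation `"cells_by_rows"` (default) if rows are cell lines,
#'   `"drugs_by_rows"` if the file is transposed.
#' @param quiet Suppress the dimension/missingness log message.
#' @return A [response_matrix()].
#' @export
read_response_matrix <- function(path, scheme,
                                 orientation = c("cells_by_rows",
                                                 "drugs_by_rows"),
                                 quiet = FALSE) {
  orientation <- match.arg(orientation)
  scheme <- as_activity_scheme(scheme)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  if (ncol(tbl) < 2) abort("File must have an identifier column plus data.")
  row_ids <- as.character(tbl[[1]])
  entity_ids <- names(tbl)[-1]
  if (anyDuplicated(row_ids)) {
    abort(paste0("Duplicate row identifiers: ",
                 paste(unique(row_ids[duplicated(row_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(entity_ids)) {
    abort(paste0("Duplicate column identifiers: ",
                 paste(unique(entity_ids[duplicated(entity_ids)]), collapse = ", ")))
  }
  raw <- as.matrix(tbl[, -1, drop = FALSE])
  sentinel <- is.na(raw) | trimws(raw) == "" |
    tolower(trimws(raw)) %in% c("na", "nan", "null")
  parsed <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(!sentinel & is.na(parsed), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("Non-numeric value at row '", row_ids[bad[1, 1]],
                 "', column '", entity_ids[bad[1, 2]], "': '",
                 raw[bad[1, , drop = FALSE]], "'"))
  }
  parsed[sentinel] <- NA_real_
  dimnames(parsed) <- list(row_ids, entity_ids)
  if (orientation == "drugs_by_rows") parsed <- t(parsed)
  m <- response_matrix(parsed, scheme,
                       transformed = scheme$name == "viability_percent")
  if (!quiet) {
    inform(paste0("Read ", nrow(parsed), " cell lines x ", ncol(parsed),
                  " drugs (", signif(100 * mean(is.na(parsed)), 3),
                  "% missing) from ", path))
  }
  m
}

#' Write a response matrix as delimited text
#'
#' Cells as rows, drugs as columns, empty string for missing entries;
#' comma-delimited for `.csv`, tab otherwise.
#'
#' @param m A [response_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(m, path) {
  tbl <- as.data.frame(m$values)
  tbl <- cbind(cell_id = rownames(m$values), tbl)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tbl, path, delim = delim, na = "")
  invisible(path)
}

#' Prune sparsely measured cell lines, then drugs
#'
#' Removes cell lines whose missing-measurement count (or fraction) exceeds
#' `cell_missing_limit`, then removes drugs whose missingness *among the
#' remaining cell lines* exceeds `drug_missing_limit`. The order is fixed:
#' cells first, drugs second. Typical settings are fractional 0.2/0.2 for
#' dense IC50 screens, 0.1/0.2 for large fold-change screens, and absolute
#' 5/5 for small viability panels.
#'
#' @param m A [response_matrix()].
#' @param cell_missing_limit,drug_missing_limit Maximum tolerated
#'   missingness per cell line / per drug; fractions in `[0, 1]` for
#'   `mode = "fractional"`, non-negative integer counts for
#'   `mode = "absolute"`. Entities strictly exceeding the limit are removed.
#' @param mode `"fractional"` or `"absolute"`.
#' @return A new, pruned [response_matrix()]; the input is unchanged.
#' @export
prune_matrix <- function(m, cell_missing_limit = 0.2,
                         drug_missing_limit = 0.2,
                         mode = c("fractional", "absolute")) {
  mode <- match.arg(mode)
  if (mode == "fractional") {
    stopifnot(cell_missing_limit >= 0, cell_missing_limit <= 1,
              drug_missing_limit >= 0, drug_missing_limit <= 1)
  } else {
    stopifnot(cell_missing_limit >= 0, drug_missing_limit >= 0,
              cell_missing_limit == round(cell_missing_limit),
              drug_missing_limit == round(drug_missing_limit))
  }
  miss <- is.na(m$values)
  cell_stat <- if (mode == "fractional") rowMeans(miss) else rowSums(miss)
  keep_cells <- cell_stat <= cell_missing_limit
  if (!any(keep_cells)) {
    abort("Pruning removed every cell line; relax `cell_missing_limit`.")
  }
  miss2 <- miss[keep_cells, , drop = FALSE]
  drug_stat <- if (mode == "fractional") colMeans(miss2) else colSums(miss2)
  keep_drugs <- drug_stat <= drug_missing_limit
  if (!any(keep_drugs)) {
    abort("Pruning removed every drug; relax `drug_missing_limit`.")
  }
  m[keep_cells, keep_drugs]
}

#' Transform raw target values onto the activity scale
#'
#' Applies the scheme transform entry-wise: molar IC50 to
#' `log10(1/IC50)` (pIC50), fold change to `-log2(fold_change)`, viability
#' unchanged. The missing mask is preserved.
#'
#' @param m A raw-scale [response_matrix()].
#' @return A transformed [response_matrix()] (`transformed = TRUE`).
#' @export
transform_targets <- function(m) {
  if (m$transformed) {
    if (m$scheme$name == "viability_percent") return(m)
    abort("Matrix is already on the activity scale.")
  }
  if (m$scheme$name %in% c("gdsc_pIC50", "prism_neglog2fc")) {
    bad <- which(!is.na(m$values) & m$values <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(paste0("Non-positive raw value at cell '",
                   rownames(m$values)[bad[1, 1]], "', drug '",
                   colnames(m$values)[bad[1, 2]],
                   "'; IC50s/fold-changes must be positive."))
    }
  }
  vals <- scheme_transform(m$values, m$scheme)
  response_matrix(vals, m$scheme, transformed = TRUE, imputed = m$imputed)
}

#' Call hits under the matrix's activity scheme
#'
#' A hit is a drug/cell-line pair whose activity satisfies the scheme's
#' rule (pIC50 > 6; inverse log2 fold-change > 1.7; viability <= 30%).
#' Missing measurements are neither hits nor non-hits and carry `NA`.
#'
#' @param m A transformed [response_matrix()].
#' @return Logical matrix aligned with `m` (`NA` where missing).
#' @export
call_hits <- function(m) {
  if (!m$transformed) abort("Transform the matrix before calling hits.")
  h <- is_hit(m$values, m$scheme)
  dimnames(h) <- dimnames(m$values)
  h
}

#' Per-drug hit prevalence
#'
#' @param hits Logical hit matrix from [call_hits()].
#' @return A tibble with one row per drug: `drug_id`, `n_hits`, `n_obs`
#'   (non-missing measurements), `prevalence` (`NA` when no measurement is
#'   available — the drug is non-evaluable).
#' @export
hit_prevalence <- function(hits) {
  n_obs <- colSums(!is.na(hits))
  n_hits <- colSums(hits, na.rm = TRUE)
  tibble(
    drug_id = colnames(hits),
    n_hits = as.integer(n_hits),
    n_obs = as.integer(n_obs),
    prevalence = ifelse(n_obs > 0, n_hits / n_obs, NA_real_)
  )
}

#' Flag selective drugs
#'
#' A drug is *selective* when it is active in strictly fewer than
#' `prevalence_limit` of the cell lines in which it was measured. Selective
#' drugs are the harder, clinically interesting prediction targets.
#' Drugs with no measurements at all are not flagged.
#'
#' @param hits Logical hit matrix from [call_hits()] over the training
#'   reference cell lines.
#' @param prevalence_limit Strict upper bound on hit prevalence; default 0.2.
#' @return Named logical vector over drugs.
#' @export
selective_drugs <- function(hits, prevalence_limit = 0.2) {
  prev <- hit_prevalence(hits)
  out <- !is.na(prev$prevalence) & prev$prevalence < prevalence_limit
  names(out) <- prev$drug_id
  out
}
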