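#' Cell-line by drug response matrices
#'
#' The central container: a numeric matrix with cell lines as rows and drugs
#' as columns, a missing mask (`NA` entries), an [activity_scheme()] tag, and
#' a record of which entries were imputed. Raw matrices hold values on the
#' scheme's native scale (molar IC50, fold change, % viability); after
#' [transform_targets()] they hold activity values and `transformed` is
#' `TRUE`.
#'
#' @param values Numeric matrix with unique row names (cell-line ids) and
#'   column names (drug ids); `NA` marks a missing measurement.
#' @param scheme An [activity_scheme()] or scheme name.
#' @param transformed Logical; `TRUE` if `values` are already on the activity
#'   scale. Viability matrices are on their activity scale natively.
#' @param imputed Optional logical matrix flagging entries that were filled
#'   by an imputation method rather than measured.
#' @return An object of class `response_matrix`.
#' @examples
#' vals <- matrix(c(95, 20, NA, 88), 2, 2,
#'                dimnames = list(c("c1", "c2"), c("d1", "d2")))
#' m <- response_matrix(vals, "viability_percent", transformed = TRUE)
#' m
#' @export
response_matrix <- function(values, scheme, transformed = FALSE,
                            imputed = NULL) {
  scheme <- as_activity_scheme(scheme)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  cells <- rownames(values)
  drugs <- colnames(values)
  if (is.null(cells) || is.null(drugs)) {
    abort("`values` must have cell-line row names and drug column names.")
  }
  if (anyDuplicated(cells)) abort("Duplicate cell-line identifiers.")
  if (anyDuplicated(drugs)) abort("Duplicate drug identifiers.")
  if (any(is.infinite(values))) {
    abort("Non-missing entries must be finite numbers.")
  }
  if (scheme$name == "viability_percent" && any(values < 0, na.rm = TRUE)) {
    abort("Viability values must be >= 0 (percent of DMSO control).")
  }
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  stopifnot(identical(dim(imputed), dim(values)))
  structure(
    list(values = values, scheme = scheme, transformed = isTRUE(transformed),
         imputed = imputed),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$values), " cell lines x ",
      ncol(x$values), " drugs (", x$scheme$name,
      if (x$transformed) ", activity scale" else ", raw scale", ")\n",
      sep = "")
  miss <- mean(is.na(x$values))
  imp <- sum(x$imputed)
  cat("  missing: ", signif(100 * miss, 3), "%",
      if (imp > 0) paste0("; imputed entries: ", imp), "\n", sep = "")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Cell-line and drug identifiers of a response matrix
#' @param m A [response_matrix()].
#' @return Character vector of identifiers.
#' @export
cell_ids <- function(m) rownames(m$values)

#' @rdname cell_ids
#' @export
drug_ids <- function(m) colnames(m$values)

#' Subset a response matrix by cell lines and/or drugs
#'
#' @param x A [response_matrix()].
#' @param cells,drugs Character ids, logical masks or indices; missing means
#'   keep all.
#' @param ... Unused.
#' @return A new `response_matrix`.
#' @export
`[.response_matrix` <- function(x, cells, drugs, ...) {
  if (missing(cells)) cells <- seq_len(nrow(x$values))
  if (missing(drugs)) drugs <- seq_len(ncol(x$values))
  response_matrix(x$values[cells, drugs, drop = FALSE], x$scheme,
                  transformed = x$transformed,
                  imputed = x$imputed[cells, drugs, drop = FALSE])
}

#' Long-format view of a response matrix
#'
#' @param x A [response_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `cell_id`, `drug_id`, `value`, `missing`,
#'   `imputed`; one row per matrix entry.
#' @export
as_tibble.response_matrix <- function(x, ...) {
  tibble(
    cell_id = rep(rownames(x$values), times = ncol(x$values)),
    drug_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    missing = as.vector(is.na(x$values)),
    imputed = as.vector(x$imputed)
  )
}

#' @export
tidy.response_matrix <- function(x, ...) as_tibble.response_matrix(x, ...)

#' @export
glance.response_matrix <- function(x, ...) {
  tibble(
    n_cells = nrow(x$values),
    n_drugs = ncol(x$values),
    scheme = x$scheme$name,
    transformed = x$transformed,
    missing_fraction = mean(is.na(x$values)),
    n_imputed = sum(x$imputed)
  )
}
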