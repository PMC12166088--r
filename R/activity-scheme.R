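#' Activity schemes: transform, hit rule and ranking direction
#'
#' An activity scheme ties together everything a dataset family needs to be
#' interpreted: how raw measurements are transformed onto an activity scale,
#' the threshold and direction that define a "hit" (an active compound), and
#' which direction of the scale means "better" when ranking drugs.
#'
#' Three schemes are supported:
#'
#' * `gdsc_pIC50` — raw values are IC50s in molar; the activity value is
#'   `log10(1 / IC50)` (a pIC50). A drug is a hit when activity exceeds 6,
#'   i.e. IC50 at or below 1 micromolar. Larger is better.
#' * `prism_neglog2fc` — raw values are post-treatment/control fold changes;
#'   the activity value is `-log2(fold_change)`. A drug is a hit when
#'   activity exceeds 1.7. Larger is better.
#' * `viability_percent` — raw values are % viability relative to the DMSO
#'   negative control and are used as-is. A drug is a hit when viability is
#'   at or below 30. Smaller is better.
#'
#' @param name One of `"gdsc_pIC50"`, `"prism_neglog2fc"`,
#'   `"viability_percent"`.
#' @return An object of class `activity_scheme`: a list with elements
#'   `name`, `hit_threshold`, `hit_direction` (`"greater"` or
#'   `"less_equal"`), and `rank_direction` (`"descending_better"` or
#'   `"ascending_better"`).
#' @examples
#' sc <- activity_scheme("gdsc_pIC50")
#' scheme_transform(1e-6, sc) # IC50 of 1 uM -> pIC50 6, the hit boundary
#' @export
activity_scheme <- function(name = c("gdsc_pIC50", "prism_neglog2fc",
                                     "viability_percent")) {
  name <- match.arg(name)
  spec <- switch(name,
    gdsc_pIC50 = list(hit_threshold = 6, hit_direction = "greater",
                      rank_direction = "descending_better"),
    prism_neglog2fc = list(hit_threshold = 1.7, hit_direction = "greater",
                           rank_direction = "descending_better"),
    viability_percent = list(hit_threshold = 30, hit_direction = "less_equal",
                             rank_direction = "ascending_better")
  )
  structure(c(list(name = name), spec), class = "activity_scheme")
}

#' @export
print.activity_scheme <- function(x, ...) {
  op <- if (x$hit_direction == "greater") ">" else "<="
  cat("<activity_scheme> ", x$name, ": hit if value ", op, " ",
      x$hit_threshold, "; ranking ",
      sub("_better", " = better", x$rank_direction), "\n", sep = "")
  invisible(x)
}

as_activity_scheme <- function(scheme) {
  if (inherits(scheme, "activity_scheme")) return(scheme)
  if (is.character(scheme) && length(scheme) == 1) return(activity_scheme(scheme))
  abort("`scheme` must be an activity_scheme object or a scheme name.")
}

#' Transform raw measurements onto a scheme's activity scale
#'
#' `gdsc_pIC50` maps molar IC50 to `log10(1/IC50)`; `prism_neglog2fc` maps
#' fold change to `-log2(fold_change)`; `viability_percent` is the identity.
#' `scheme_inverse()` undoes the transform.
#'
#' @param x Numeric vector of raw (or, for the inverse, activity) values.
#' @param scheme An [activity_scheme()].
#' @return Numeric vector, same length as `x`; `NA` passes through.
#' @export
scheme_transform <- function(x, scheme) {
  scheme <- as_activity_scheme(scheme)
  switch(scheme$name,
    gdsc_pIC50 = log10(1 / x),
    prism_neglog2fc = -log2(x),
    viability_percent = x
  )
}

#' @rdname scheme_transform
#' @export
scheme_inverse <- function(x, scheme) {
  scheme <- as_activity_scheme(scheme)
  switch(scheme$name,
    gdsc_pIC50 = 10^(-x),
    prism_neglog2fc = 2^(-x),
    viability_percent = x
  )
}

#' Apply a scheme's hit rule to activity values
#'
#' @param x Numeric vector on the scheme's activity scale.
#' @param scheme An [activity_scheme()].
#' @return Logical vector; `NA` where `x` is `NA` (missing measurements are
#'   neither hits nor non-hits).
#' @export
is_hit <- function(x, scheme) {
  scheme <- as_activity_scheme(scheme)
  if (scheme$hit_direction == "greater") x > scheme$hit_threshold
  else x <= scheme$hit_threshold
}

# order ids best-first under the scheme's rank direction, ties by id
rank_drug_ids <- function(values, scheme) {
  scheme <- as_activity_scheme(scheme)
  ids <- names(values)
  if (is.null(ids)) abort("`values` must be a named vector of activities.")
  keep <- !is.na(values)
  values <- values[keep]
  ids <- ids[keep]
  key <- if (scheme$rank_direction == "descending_better") -values else values
  ids[order(key, ids)]
}
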