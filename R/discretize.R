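# Quantile discretization of continuous variables.

#' Fit equal-probability quantile cuts from training values
#'
#' Returns `n_levels - 1` empirical quantile thresholds splitting the
#' training distribution into (approximately) equal-probability bins.
#' Quantiles use the standard linear-interpolation definition
#' (`stats::quantile` type 7), recorded in the serialized schema.
#'
#' @param x numeric training values; `NA`s are skipped.
#' @param n_levels number of bins (>= 1).
#' @return numeric vector of `n_levels - 1` strictly increasing cuts.
#' @export
fit_quantile_cuts <- function(x, n_levels) {
  stopifnot(n_levels >= 1)
  x <- x[!is.na(x)]
  if (n_levels == 1L) return(numeric(0))
  if (length(unique(x)) < n_levels)
    abort_als(paste("fewer than %d distinct values: treat the variable as",
                    "categorical instead of discretizing"), n_levels)
  probs <- seq_len(n_levels - 1L) / n_levels
  cuts <- unname(quantile(x, probs, type = 7))
  if (is.unsorted(cuts, strictly = TRUE))
    abort_als("tied quantiles: too many repeated values for %d levels",
              n_levels)
  cuts
}

#' Discretize values against a variable spec
#'
#' Intervals are right-closed at each cut: with cuts c1 < c2 the bins are
#' (-Inf, c1], (c1, c2], (c2, Inf), so a value exactly equal to a cut falls
#' in the lower bin.
#'
#' @param x numeric vector (NA allowed, propagated).
#' @param spec a [variable_spec()] with kind `"discretized-continuous"`.
#' @return character vector of level labels.
#' @export
discretize <- function(x, spec) {
  if (spec$kind != "discretized-continuous")
    abort_als("variable '%s' is categorical; discretize() does not apply",
              spec$name)
  if (!is.numeric(x)) abort_als("discretize: non-numeric input for '%s'",
                                spec$name)
  if (length(spec$levels) != length(spec$cuts) + 1L)
    abort_als("variable '%s': cuts not set (fit them first)", spec$name)
  spec$levels[cut_index(x, spec$cuts)]
}

#' Refit the quantile cuts of a schema from training data
#'
#' For every discretized-continuous variable present in `values`, replaces
#' the schema's cuts by quantile cuts fitted on the training values,
#' keeping the declared number of levels. Variables listed in `frozen` keep
#' their shipped cuts.
#'
#' @param schema a `cohort_schema`.
#' @param values named list (or data.frame) of raw numeric training values
#'   per variable name.
#' @param frozen character vector of variable names whose cuts are kept.
#' @return the updated schema.
#' @export
fit_schema_cuts <- function(schema, values, frozen = character(0)) {
  for (nm in names(schema$variables)) {
    v <- schema$variables[[nm]]
    if (v$kind != "discretized-continuous" || nm %in% frozen) next
    if (is.null(values[[nm]]) || all(is.na(values[[nm]]))) next
    schema$variables[[nm]]$cuts <-
      fit_quantile_cuts(values[[nm]], length(v$levels))
  }
  schema
}
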