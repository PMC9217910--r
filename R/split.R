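# Balance-checked train/test splitting at patient level.

# Patient-level summary used for balance checks: baseline visit values
# plus the survival outcome. Continuous columns keep their raw values
# when available so that Kruskal-Wallis operates on the raw scale.
patient_table <- function(cohort, variables = NULL) {
  base <- baseline_visits(cohort)
  tab <- merge(base, cohort$outcomes, by = "patient_id", sort = FALSE)
  # tbv is structurally constant ("baseline") on first visits
  drop <- c("patient_id", "visit_time", "tbv", "tbv_months")
  if (is.null(variables))
    variables <- setdiff(names(tab), drop)
  # prefer raw numeric twin columns over discretized labels
  raw_twin <- paste0(variables, "_raw")
  variables <- ifelse(raw_twin %in% names(tab), raw_twin, variables)
  tab[, c("patient_id", unique(variables)), drop = FALSE]
}

#' Balance-checked random train/test split
#'
#' Splits a cohort into train and test partitions at the patient level
#' (never separating visits of one patient), in the given proportion.
#' `n_attempts` random splits are drawn; for each, every baseline variable
#' and the survival outcome are compared between partitions with a
#' Kruskal-Wallis test (continuous) or a chi-squared test (categorical),
#' and the split maximizing the minimum p-value across variables is kept.
#' Variables observed at a single level are skipped with a warning.
#'
#' @param cohort an `als_cohort` after [derive_temporal_vars()].
#' @param ratio training fraction, default 0.8.
#' @param n_attempts number of random splits scored, default 50.
#' @param alpha significance level for the balance report, default 0.01.
#' @param seed integer seed; same seed, same split.
#' @return list with `train` and `test` (`als_cohort`s) and `report`, a
#'   data.frame of per-variable test name and p-value for the selected
#'   split, plus attributes `min_p` and `balanced` (no p below `alpha`).
#' @export
balanced_split <- function(cohort, ratio = 0.8, n_attempts = 50,
                           alpha = 0.01, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1, n_attempts >= 1)
  ids <- cohort$outcomes$patient_id
  if (length(ids) < 10) abort_als("need at least 10 patients to split")
  n_train <- round(length(ids) * ratio)
  tab <- patient_table(cohort)
  vars <- setdiff(names(tab), "patient_id")
  usable <- vars[vapply(vars, function(v) {
    obs <- tab[[v]][!is.na(tab[[v]])]
    ok <- length(unique(obs)) > 1
    if (!ok) warn_als("balanced_split: '%s' has a single observed level; skipped", v)
    ok
  }, TRUE)]

  set.seed(seed)
  best <- NULL
  for (a in seq_len(n_attempts)) {
    train_ids <- sample(ids, n_train)
    grp <- tab$patient_id %in% train_ids
    ps <- vapply(usable, function(v) split_balance_p(tab[[v]], grp), 0)
    if (is.null(best) || min(ps) > best$min_p)
      best <- list(train_ids = train_ids, p = ps, min_p = min(ps))
  }
  report <- data.frame(
    variable = sub("_raw$", "", usable),
    test = ifelse(vapply(usable, function(v) is.numeric(tab[[v]]), TRUE),
                  "kruskal-wallis", "chi-squared"),
    p_value = unname(best$p), row.names = NULL)
  attr(report, "min_p") <- best$min_p
  attr(report, "balanced") <- best$min_p >= alpha
  list(train = subset_cohort(cohort, best$train_ids),
       test = subset_cohort(cohort, setdiff(ids, best$train_ids)),
       report = report)
}

split_balance_p <- function(x, grp) {
  ok <- !is.na(x)
  x <- x[ok]; g <- grp[ok]
  if (length(unique(g)) < 2) return(0)
  if (is.numeric(x)) {
    stats::kruskal.test(x, factor(g))$p.value
  } else {
    tbl <- table(x, g)
    tbl <- tbl[rowSums(tbl) > 0, , drop = FALSE]
    if (nrow(tbl) < 2) return(1)
    suppressWarnings(stats::chisq.test(tbl)$p.value)
  }
}
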