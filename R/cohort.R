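# Longitudinal cohort container: one row per patient-visit plus a
# patient-level survival outcome table.

#' Construct a longitudinal ALS cohort
#'
#' @param visits data.frame, one row per patient-visit, with columns
#'   `patient_id`, `visit_time` (months since disease onset) and one column
#'   per schema variable that is observed at visits. Missing values are
#'   `NA`.
#' @param outcomes data.frame with one row per patient: `patient_id`,
#'   `survival_time` (months from onset to tracheostomy/death or
#'   censoring), `event` (1 = tracheostomy/death, 0 = censored).
#' @return an object of class `als_cohort`.
#' @export
als_cohort <- function(visits, outcomes) {
  stopifnot(is.data.frame(visits), is.data.frame(outcomes))
  for (col in c("patient_id", "visit_time"))
    if (!col %in% names(visits))
      abort_als("visits table lacks required column '%s'", col)
  for (col in c("patient_id", "survival_time", "event"))
    if (!col %in% names(outcomes))
      abort_als("outcomes table lacks required column '%s'", col)
  visits$patient_id <- as.character(visits$patient_id)
  outcomes$patient_id <- as.character(outcomes$patient_id)
  if (anyDuplicated(outcomes$patient_id))
    abort_als("outcomes table has duplicated patient ids")
  orphan <- setdiff(visits$patient_id, outcomes$patient_id)
  if (length(orphan) > 0)
    abort_als("visits without outcome row: %s",
              paste(head(orphan, 5), collapse = ", "))
  structure(list(visits = visits, outcomes = outcomes),
            class = "als_cohort")
}

#' @export
print.als_cohort <- function(x, ...) {
  cat(sprintf("ALS cohort: %d patients, %d visits, %.0f%% deceased\n",
              nrow(x$outcomes), nrow(x$visits),
              100 * mean(x$outcomes$event)))
  invisible(x)
}

n_patients <- function(cohort) nrow(cohort$outcomes)

#' Derive the temporal variables tso and tbv from visit times
#'
#' Sorts each patient's visits by time and adds `tso_months` (time since
#' onset) and `tbv_months` (time between consecutive visits; `NA` on the
#' first visit, whose discretized tbv level is the distinguished
#' `"baseline"` label). Validates visit ordering against the survival
#' outcome.
#'
#' @param cohort an `als_cohort` whose visits carry `visit_time` in
#'   onset-relative months.
#' @param tol numeric tolerance for survival-time consistency checks.
#' @return the cohort with temporal columns filled in.
#' @export
derive_temporal_vars <- function(cohort, tol = 1e-6) {
  v <- cohort$visits
  if (any(is.na(v$visit_time))) abort_als("visit_time contains NA")
  if (any(v$visit_time < 0)) abort_als("negative time since onset")
  ord <- order(v$patient_id, v$visit_time)
  v <- v[ord, , drop = FALSE]
  sp <- split(seq_len(nrow(v)), v$patient_id)
  v$tso_months <- v$visit_time
  v$tbv_months <- NA_real_
  for (pid in names(sp)) {
    idx <- sp[[pid]]
    tt <- v$visit_time[idx]
    if (anyDuplicated(tt))
      abort_als("patient '%s' has duplicated visit times", pid)
    if (length(idx) > 1)
      v$tbv_months[idx[-1]] <- diff(tt)
    out <- cohort$outcomes[cohort$outcomes$patient_id == pid, ]
    if (out$survival_time < max(tt) - tol)
      abort_als("patient '%s': survival_time %.2f precedes last visit %.2f",
                pid, out$survival_time, max(tt))
  }
  rownames(v) <- NULL
  cohort$visits <- v
  cohort
}

#' Discretize a cohort's continuous columns against a schema
#'
#' Replaces every discretized-continuous variable column by its level
#' labels (raw values preserved in a `<name>_raw` column) and adds discrete
#' `tso` / `tbv` columns from `tso_months` / `tbv_months`; the first visit
#' of each patient receives the `"baseline"` tbv level.
#'
#' @param cohort an `als_cohort` after [derive_temporal_vars()].
#' @param schema a `cohort_schema` with cuts set for every
#'   discretized-continuous variable present.
#' @return the discretized cohort.
#' @export
discretize_cohort <- function(cohort, schema) {
  v <- cohort$visits
  if (is.null(v$tso_months))
    abort_als("run derive_temporal_vars() before discretize_cohort()")
  for (nm in names(schema$variables)) {
    spec <- schema$variables[[nm]]
    if (spec$kind != "discretized-continuous") next
    if (nm == TSO_VAR) {
      v$tso <- discretize(v$tso_months, spec)
    } else if (nm == TBV_VAR) {
      v$tbv <- ifelse(is.na(v$tbv_months), TBV_BASELINE,
                      discretize(v$tbv_months, spec))
    } else if (nm %in% names(v) && is.numeric(v[[nm]])) {
      v[[paste0(nm, "_raw")]] <- v[[nm]]
      v[[nm]] <- discretize(v[[nm]], spec)
    }
  }
  # validate categorical levels
  for (nm in intersect(names(schema$variables), names(v))) {
    lv <- var_levels(schema, nm, as_parent = TRUE)
    bad <- !is.na(v[[nm]]) & !(v[[nm]] %in% lv)
    if (any(bad))
      abort_als("variable '%s': unknown level(s) %s", nm,
                paste(unique(v[[nm]][bad]), collapse = ", "))
  }
  cohort$visits <- v
  cohort
}

#' First visit of every patient
#'
#' @param cohort an `als_cohort` after [derive_temporal_vars()].
#' @return data.frame of baseline visit rows (one per patient).
#' @export
baseline_visits <- function(cohort) {
  v <- cohort$visits
  first <- !duplicated(v$patient_id) # visits are sorted by (patient, time)
  v[first, , drop = FALSE]
}

#' Restrict a cohort to a set of patients
#' @param cohort an `als_cohort`.
#' @param ids character vector of patient ids.
#' @export
subset_cohort <- function(cohort, ids) {
  als_cohort(cohort$visits[cohort$visits$patient_id %in% ids, , drop = FALSE],
             cohort$outcomes[cohort$outcomes$patient_id %in% ids, ,
                             drop = FALSE])
}

#' Read / write a cohort as a delimited visit table
#'
#' The on-disk format is a single long-format CSV with a header: one row
#' per visit, columns `patient_id`, `visit_time` plus variable columns,
#' with the patient-level `survival_time` and `event` columns repeated on
#' every row. Missing values are empty cells.
#'
#' @param path CSV file path.
#' @return an `als_cohort` (for `read_cohort_csv`).
#' @export
read_cohort_csv <- function(path) {
  tab <- read.csv(path, na.strings = c("", "NA"), check.names = FALSE,
                  colClasses = "character")
  numeric_cols <- c("visit_time", "survival_time", "event", "tso_months",
                    "tbv_months", grep("_raw$", names(tab), value = TRUE))
  for (col in intersect(numeric_cols, names(tab)))
    tab[[col]] <- as.numeric(tab[[col]])
  for (col in c("survival_time", "event"))
    if (!col %in% names(tab))
      abort_als("'%s': missing required column '%s'", path, col)
  out <- tab[!duplicated(tab$patient_id),
             c("patient_id", "survival_time", "event")]
  keep <- setdiff(names(tab), c("survival_time", "event"))
  als_cohort(tab[, keep, drop = FALSE], out)
}

#' @rdname read_cohort_csv
#' @param cohort an `als_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  tab <- merge(cohort$visits, cohort$outcomes, by = "patient_id",
               sort = FALSE)
  tab <- tab[order(tab$patient_id, tab$visit_time), , drop = FALSE]
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
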