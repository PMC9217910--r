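# Transition dataset: (state at t-1, state at t) pairs from consecutive
# visits, plus baseline rows for the static layer.

#' Build the transition dataset from a discretized cohort
#'
#' Every pair of consecutive visits of a patient contributes one row:
#' the `from` frame holds the slice-(t-1) values of all admissible parents
#' (statics, dynamic variables, tbv, tso) and the `to` frame the slice-t
#' values of all children (tbv, dynamic variables, survival). The survival
#' child is `"alive"` on every observed visit; for deceased patients one
#' extra terminal row is appended at the survival time with
#' survival = `"dead"` and all other slice-t values missing, so the dataset
#' contains alive-to-dead examples. Censored patients contribute no rows
#' past their last visit. Missing values are preserved (available-cases
#' fitting handles them downstream).
#'
#' @param cohort a discretized `als_cohort`.
#' @param schema the `cohort_schema` used for discretization.
#' @return a list of class `transition_dataset`: `from`, `to`
#'   (data.frames), `tbv_raw` (continuous months of the slice-t tbv, used
#'   for empirical tbv pools), `baseline` (one row per patient: statics
#'   and first-visit values, for static-layer fitting), `n` (row count).
#' @export
build_transition_dataset <- function(cohort, schema) {
  v <- cohort$visits
  if (is.null(v$tso) || is.null(v$tbv))
    abort_als("cohort is not discretized; run discretize_cohort() first")
  pvars <- dbn_parents(schema)
  cvars <- dbn_children(schema)
  for (nm in setdiff(union(pvars, cvars), c(SURVIVAL_VAR, names(v))))
    v[[nm]] <- NA_character_

  no_visit <- setdiff(cohort$outcomes$patient_id, v$patient_id)
  if (length(no_visit) > 0)
    warn_als("skipping %d patient(s) without visits", length(no_visit))

  same_next <- v$patient_id == c(v$patient_id[-1], NA)
  i_from <- which(same_next)        # rows with a successor visit
  i_to <- i_from + 1L

  from <- v[i_from, pvars, drop = FALSE]
  to <- v[i_to, setdiff(cvars, SURVIVAL_VAR), drop = FALSE]
  to[[SURVIVAL_VAR]] <- "alive"
  tbv_raw <- v$tbv_months[i_to]

  # terminal death pseudo-visit for event patients
  last <- which(!same_next | is.na(same_next))
  last_pid <- v$patient_id[last]
  out <- cohort$outcomes[match(last_pid, cohort$outcomes$patient_id), ]
  died <- out$event == 1
  if (any(died)) {
    dl <- last[died]
    dfrom <- v[dl, pvars, drop = FALSE]
    tbv_death <- pmax(out$survival_time[died] - v$tso_months[dl], 1e-6)
    dto <- as.data.frame(setNames(
      rep(list(NA_character_), length(cvars)), cvars))[rep(1, length(dl)), ,
                                                       drop = FALSE]
    dto$tbv <- discretize(tbv_death, schema$variables[[TBV_VAR]])
    dto$survival <- "dead"
    from <- rbind(from, dfrom)
    to <- rbind(to, dto[, names(to), drop = FALSE])
    tbv_raw <- c(tbv_raw, tbv_death)
  }
  rownames(from) <- rownames(to) <- NULL

  base <- baseline_visits(cohort)
  structure(list(from = from, to = to, tbv_raw = tbv_raw,
                 baseline = base, n = nrow(from)),
            class = "transition_dataset")
}

#' @export
print.transition_dataset <- function(x, ...) {
  cat(sprintf("transition dataset: %d rows (%d deaths), %d baseline rows\n",
              x$n, sum(x$to$survival == "dead", na.rm = TRUE),
              nrow(x$baseline)))
  invisible(x)
}

# integer-coded family view: child y and parent matrix X for one family.
# Static children are fitted on baseline rows; dynamic/tbv/survival
# children on transition rows (child at slice t, parents at slice t-1).
family_view <- function(tdata, schema, child, parents) {
  static_child <- child %in% schema$static_names
  frame <- if (static_child) tdata$baseline else tdata$from
  ylv <- var_levels(schema, child, as_parent = FALSE)
  yraw <- if (static_child) tdata$baseline[[child]] else tdata$to[[child]]
  y <- match(yraw, ylv)
  X <- NULL
  card <- integer(0)
  plevels <- list()
  for (p in parents) {
    lv <- var_levels(schema, p, as_parent = !static_child)
    X <- cbind(X, match(frame[[p]], lv))
    card <- c(card, length(lv))
    plevels[[p]] <- lv
  }
  list(y = y, X = X, r = length(ylv), child_levels = ylv,
       parent_card = card, parent_levels = plevels)
}
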