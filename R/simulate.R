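# Monte-Carlo forward simulation of disease trajectories from a single
# complete baseline visit.

#' Simulation configuration
#'
#' @param n_reps number of independent repetitions per patient
#'   (default 100).
#' @param max_steps maximum number of simulated visits per repetition
#'   (default 40); a repetition also stops at the simulated death.
#' @param seed master integer seed. Every patient draws from an own
#'   stream derived from the master seed and the patient id, so per-patient
#'   results do not depend on cohort ordering.
#' @param tbv_sampling `"bin-empirical"`: convert a sampled tbv bin to
#'   months by drawing from the stored training values of that bin;
#'   `"bin-uniform"`: draw uniformly within the bin bounds (used when no
#'   empirical pool is available, e.g. for purely synthetic models).
#' @param record_states keep the full simulated state sequences (memory
#'   heavy for large cohorts); event times are always kept.
#' @return a named list.
#' @export
sim_config <- function(n_reps = 100L, max_steps = 40L, seed = 1L,
                       tbv_sampling = c("bin-empirical", "bin-uniform"),
                       record_states = FALSE) {
  stopifnot(n_reps >= 1, max_steps >= 1)
  list(n_reps = as.integer(n_reps), max_steps = as.integer(max_steps),
       seed = as.integer(seed), tbv_sampling = match.arg(tbv_sampling),
       record_states = isTRUE(record_states))
}

# vectorized categorical sampling: one draw per row of probability matrix P
sample_rows <- function(P) {
  r <- ncol(P)
  if (r == 1) return(rep(1L, nrow(P)))
  cs <- P
  for (j in 2:r) cs[, j] <- cs[, j - 1] + P[, j]
  u <- runif(nrow(P)) * cs[, r] # guard tiny rounding in the last column
  idx <- rep(1L, nrow(P))
  for (j in seq_len(r - 1)) idx <- idx + (u > cs[, j])
  idx
}

# draw continuous months for sampled tbv bins
sample_tbv_months <- function(model, bins, mode) {
  out <- numeric(length(bins))
  bounds <- model$tbv$bounds
  for (b in unique(bins)) {
    sel <- bins == b
    pool <- model$tbv$pools[[b]]
    if (mode == "bin-empirical" && length(pool) > 0) {
      out[sel] <- pool[ceiling(runif(sum(sel)) * length(pool))]
    } else {
      out[sel] <- runif(sum(sel), bounds[b], bounds[b + 1])
    }
  }
  pmax(out, 1e-3)
}

# one synchronous transition of all rows of an integer-coded state matrix.
# S columns follow dbn_parents(schema); tso_cont is the continuous time
# since onset. All children condition on the OLD state (slice t-1).
step_states <- function(model, S, tso_cont, mode) {
  schema <- model$schema
  pvars <- colnames(S)
  cfg_of <- function(cpt) {
    if (length(cpt$parents) == 0) return(rep(1L, nrow(S)))
    config_index(S[, cpt$parents, drop = FALSE], cpt$parent_card)
  }
  # tbv first: it advances the clock
  cpt_tbv <- model$cpts[[TBV_VAR]]
  bins <- sample_rows(cpt_tbv$prob[cfg_of(cpt_tbv), , drop = FALSE])
  tbv_months <- sample_tbv_months(model, bins, mode)
  tso_new <- tso_cont + tbv_months
  S_new <- S
  S_new[, TBV_VAR] <- bins
  S_new[, TSO_VAR] <- cut_index(tso_new, schema$variables[[TSO_VAR]]$cuts)
  for (child in schema$dynamic_names) {
    cpt <- model$cpts[[child]]
    S_new[, child] <- sample_rows(cpt$prob[cfg_of(cpt), , drop = FALSE])
  }
  cpt_s <- model$cpts[[SURVIVAL_VAR]]
  dead <- sample_rows(cpt_s$prob[cfg_of(cpt_s), , drop = FALSE]) == 2L
  list(S = S_new, tso_cont = tso_new, dead = dead)
}

# integer-code one baseline row against the parent-level sets
encode_baseline <- function(model, baseline) {
  schema <- model$schema
  pvars <- dbn_parents(schema)
  need <- c(pvars, "tso_months")
  missing <- need[vapply(need, function(nm)
    is.null(baseline[[nm]]) || is.na(baseline[[nm]]), TRUE)]
  if (length(missing) > 0)
    abort_als("incomplete baseline: missing %s (no missing values are allowed in the starting visit)",
              paste(missing, collapse = ", "))
  codes <- vapply(pvars, function(nm) {
    lv <- var_levels(schema, nm, as_parent = TRUE)
    m <- match(as.character(baseline[[nm]]), lv)
    if (is.na(m)) abort_als("baseline: unknown level '%s' for '%s'",
                            baseline[[nm]], nm)
    m
  }, 0L)
  list(codes = codes, tso = as.numeric(baseline[["tso_months"]]))
}

#' Simulate one step of the two-slice DBN
#'
#' Samples the slice-t state given a complete slice-(t-1) state: statics
#' are copied, the tbv bin is sampled from its table and converted to
#' continuous months, tso accumulates deterministically and is
#' re-discretized, and every dynamic and outcome variable is sampled from
#' its conditional table given the slice-(t-1) values. Uses the current
#' RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param model a `two_slice_dbn`.
#' @param state one-row data.frame (or named list) with all schema
#'   variables at their discrete levels plus `tso_months`; must be alive
#'   and complete.
#' @param n number of independent draws.
#' @param tbv_sampling see [sim_config()].
#' @return data.frame of `n` sampled slice-t states (discrete levels,
#'   `tbv_months`, `tso_months`, and `survival`).
#' @export
simulate_step <- function(model, state, n = 1,
                          tbv_sampling = c("bin-empirical", "bin-uniform")) {
  mode <- match.arg(tbv_sampling)
  schema <- model$schema
  enc <- encode_baseline(model, state)
  pvars <- dbn_parents(schema)
  S <- matrix(enc$codes, nrow = n, ncol = length(pvars), byrow = TRUE,
              dimnames = list(NULL, pvars))
  st <- step_states(model, S, rep(enc$tso, n), mode)
  out <- as.data.frame(lapply(pvars, function(nm) {
    lv <- var_levels(schema, nm, as_parent = TRUE)
    lv[st$S[, nm]]
  }), col.names = pvars)
  out$tso_months <- st$tso_cont
  out$tbv_months <- st$tso_cont - enc$tso
  out$survival <- ifelse(st$dead, "dead", "alive")
  out
}

#' Simulate the follow-up of one patient
#'
#' Runs `n_reps` independent Monte-Carlo repetitions from the patient's
#' baseline visit, each evolving for up to `max_steps` simulated visits or
#' until the simulated death, and records per repetition the first time
#' each MiToS domain becomes impaired and the death time. A domain already
#' impaired at baseline gets its event time at the baseline tso.
#'
#' @param model a `two_slice_dbn`.
#' @param baseline one-row data.frame: discretized schema variables plus
#'   `tso_months` (and optionally `patient_id`). Must be complete.
#' @param config a [sim_config()].
#' @return an object of class `sim_followups`: `event_times` (matrix
#'   n_reps x outcomes, months since onset, NA if the outcome never
#'   occurred), `terminated_by` (`"death"` or `"max_steps"` per rep),
#'   `states` (long data.frame or NULL), `patient_id`, `config`.
#' @export
simulate_patient <- function(model, baseline, config = sim_config()) {
  schema <- model$schema
  pid <- as.character(baseline[["patient_id"]] %||% "patient")
  enc <- encode_baseline(model, baseline)
  set.seed(derive_seed(config$seed, pid))
  n <- config$n_reps
  pvars <- dbn_parents(schema)
  S <- matrix(enc$codes, nrow = n, ncol = length(pvars), byrow = TRUE,
              dimnames = list(NULL, pvars))
  tso_cont <- rep(enc$tso, n)
  outcomes <- c(MITOS_VARS, "death")
  et <- matrix(NA_real_, n, length(outcomes),
               dimnames = list(NULL, outcomes))
  for (fl in MITOS_VARS)
    if (S[1, fl] == 2L) et[, fl] <- enc$tso
  alive <- rep(TRUE, n)
  states <- if (config$record_states) vector("list", config$max_steps + 1L)
  if (config$record_states)
    states[[1]] <- decode_states(schema, S, tso_cont, rep(0L, n),
                                 alive = rep(TRUE, n))
  for (step in seq_len(config$max_steps)) {
    act <- which(alive)
    if (length(act) == 0) break
    st <- step_states(model, S[act, , drop = FALSE], tso_cont[act],
                      config$tbv_sampling)
    S[act, ] <- st$S
    tso_cont[act] <- st$tso_cont
    for (fl in MITOS_VARS) {
      fire <- act[st$S[, fl] == 2L & is.na(et[act, fl])]
      et[fire, fl] <- tso_cont[fire]
    }
    died <- act[st$dead]
    et[died, "death"] <- tso_cont[died]
    alive[died] <- FALSE
    if (config$record_states)
      states[[step + 1L]] <- decode_states(schema, S[act, , drop = FALSE],
                                           tso_cont[act], rep(step, length(act)),
                                           alive = !st$dead, reps = act)
  }
  res <- list(patient_id = pid,
              event_times = et,
              terminated_by = ifelse(is.na(et[, "death"]), "max_steps",
                                     "death"),
              states = if (config$record_states)
                do.call(rbind, states[!vapply(states, is.null, TRUE)]),
              config = config)
  class(res) <- "sim_followups"
  res
}

decode_states <- function(schema, S, tso_cont, step, alive,
                          reps = seq_len(nrow(S))) {
  out <- as.data.frame(lapply(colnames(S), function(nm) {
    lv <- var_levels(schema, nm, as_parent = TRUE)
    lv[S[, nm]]
  }), col.names = colnames(S))
  out$rep <- reps
  out$step <- step
  out$tso_months <- tso_cont
  out$survival <- ifelse(alive, "alive", "dead")
  out
}

#' @export
print.sim_followups <- function(x, ...) {
  cat(sprintf("simulated follow-up of '%s': %d reps, %.0f%% reached death\n",
              x$patient_id, nrow(x$event_times),
              100 * mean(x$terminated_by == "death")))
  invisible(x)
}

#' Simulate a whole cohort of baselines
#'
#' @param model a `two_slice_dbn`.
#' @param baselines data.frame of baseline visit rows (one per patient,
#'   e.g. from [baseline_visits()]), each complete.
#' @param config a [sim_config()]; each patient uses an own stream derived
#'   from `config$seed` and the patient id.
#' @return an object of class `cohort_sim`: named list `followups` of
#'   `sim_followups`, plus `n_reps` and `patient_ids`.
#' @export
simulate_cohort <- function(model, baselines, config = sim_config()) {
  fus <- lapply(seq_len(nrow(baselines)), function(i)
    simulate_patient(model, baselines[i, , drop = FALSE], config))
  ids <- vapply(fus, `[[`, "", "patient_id")
  names(fus) <- ids
  structure(list(followups = fus, n_reps = config$n_reps,
                 patient_ids = ids, config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("cohort simulation: %d patients x %d reps\n",
              length(x$followups), x$n_reps))
  invisible(x)
}

#' Cumulative risk curve of one simulated patient
#'
#' At each grid time, the fraction of repetitions whose event time for the
#' outcome is at or before that time; non-decreasing in time.
#'
#' @param followups a `sim_followups`.
#' @param outcome one of the MiToS flag names or `"death"`.
#' @param time_grid increasing numeric vector (months since onset).
#' @return numeric vector of probabilities along the grid.
#' @export
risk_curve <- function(followups, outcome, time_grid) {
  if (is.unsorted(time_grid)) abort_als("time_grid must be increasing")
  et <- followups$event_times
  if (nrow(et) == 0) abort_als("empty follow-up list")
  if (!outcome %in% colnames(et))
    abort_als("unknown outcome '%s'", outcome)
  vapply(time_grid, function(tau)
    mean(!is.na(et[, outcome]) & et[, outcome] <= tau), 0)
}

#' Long-table export of simulated events
#'
#' @param sim a `cohort_sim`.
#' @return data.frame (patient_id, rep, outcome, time).
#' @export
sim_events_table <- function(sim) {
  do.call(rbind, lapply(sim$followups, function(fu) {
    et <- fu$event_times
    idx <- which(!is.na(et), arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    data.frame(patient_id = fu$patient_id, rep = idx[, 1],
               outcome = colnames(et)[idx[, 2]],
               time = et[idx], row.names = NULL)
  }))
}
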