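# Discrimination and calibration of simulated prognoses against observed
# trajectories.

#' Observed outcome labels of a cohort
#'
#' For each patient and outcome, the observed event time in months since
#' onset (first visit at which the MiToS flag is impaired; survival time
#' for death) and the event indicator. Patients never observed impaired
#' are censored at their survival/censoring time.
#'
#' @param cohort a discretized `als_cohort`.
#' @return data.frame (patient_id, outcome, time, status) with status 1 =
#'   event, 0 = censored.
#' @export
extract_labels <- function(cohort) {
  v <- cohort$visits
  out <- cohort$outcomes
  labs <- list()
  for (fl in intersect(MITOS_VARS, names(v))) {
    hit <- v[!is.na(v[[fl]]) & v[[fl]] == "1", c("patient_id", "tso_months")]
    first_hit <- tapply(hit$tso_months, hit$patient_id, min)
    time <- out$survival_time
    status <- rep(0L, nrow(out))
    m <- match(out$patient_id, names(first_hit))
    has <- !is.na(m)
    time[has] <- unname(first_hit[m[has]])
    status[has] <- 1L
    labs[[fl]] <- data.frame(patient_id = out$patient_id, outcome = fl,
                             time = time, status = status)
  }
  labs$death <- data.frame(patient_id = out$patient_id, outcome = "death",
                           time = out$survival_time,
                           status = as.integer(out$event))
  do.call(rbind, c(labs, list(make.row.names = FALSE)))
}

#' Time-dependent AU-ROC at one evaluation time
#'
#' Cumulative/dynamic convention: cases are patients with an observed
#' event at or before `tau`; controls are patients still event-free and
#' under observation at `tau`; patients censored before `tau` are excluded
#' (set `censored_as_controls = TRUE` for the alternative convention).
#' The AU-ROC is the Mann-Whitney probability that a random case receives
#' a higher risk score than a random control, ties counted one half.
#'
#' @param scores numeric risk score per patient (higher = riskier).
#' @param time observed event/censoring time per patient.
#' @param status 1 = event, 0 = censored.
#' @param tau evaluation time (months since onset).
#' @param censored_as_controls include patients censored before `tau` as
#'   controls (default FALSE).
#' @return list(auc, n_cases, n_controls); `auc` is NA when either group
#'   is empty.
#' @export
time_dependent_auroc <- function(scores, time, status, tau,
                                 censored_as_controls = FALSE) {
  case <- status == 1 & time <= tau
  control <- time > tau
  if (censored_as_controls) control <- control | (status == 0 & time <= tau)
  n1 <- sum(case); n0 <- sum(control)
  if (n1 == 0 || n0 == 0)
    return(list(auc = NA_real_, n_cases = n1, n_controls = n0))
  s <- c(scores[case], scores[control])
  rk <- rank(s) # average ranks implement the half-tie convention
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(auc = u / (n1 * n0), n_cases = n1, n_controls = n0)
}

#' AU-ROC over a time grid for one outcome
#'
#' At each grid time, each patient's risk score is their simulated
#' cumulative risk at that time (fraction of repetitions with the outcome
#' by then), compared against the observed labels.
#'
#' @param sim a `cohort_sim`.
#' @param labels data.frame from [extract_labels()] (all outcomes; the
#'   relevant one is selected).
#' @param outcome one of the MiToS flags or `"death"`.
#' @param time_grid evaluation times, default 3-month steps from 6 to 96.
#' @param censored_as_controls see [time_dependent_auroc()].
#' @return data.frame (tau, auc, n_cases, n_controls); undefined times
#'   (no cases or no controls) carry NA auc.
#' @export
auroc_grid <- function(sim, labels, outcome,
                       time_grid = seq(6, 96, by = 3),
                       censored_as_controls = FALSE) {
  lab <- labels[labels$outcome == outcome, ]
  lab <- lab[match(sim$patient_ids, lab$patient_id), ]
  if (anyNA(lab$patient_id))
    abort_als("labels missing for some simulated patients")
  risks <- vapply(sim$followups, function(fu)
    risk_curve(fu, outcome, time_grid), numeric(length(time_grid)))
  risks <- matrix(risks, nrow = length(time_grid))
  res <- lapply(seq_along(time_grid), function(i)
    time_dependent_auroc(risks[i, ], lab$time, lab$status, time_grid[i],
                         censored_as_controls))
  data.frame(tau = time_grid,
             auc = vapply(res, `[[`, 0, "auc"),
             n_cases = vapply(res, `[[`, 0L, "n_cases"),
             n_controls = vapply(res, `[[`, 0L, "n_controls"))
}

#' Integrated (time-averaged) AU-ROC up to a horizon
#'
#' Trapezoidal integral of the defined AU-ROC values over the grid up to
#' the horizon, divided by the integrated time span, yielding a
#' time-averaged AU-ROC in [0, 1]. Leading undefined grid points (no
#' cases yet) are skipped: integration starts at the first defined point.
#'
#' @param grid data.frame from [auroc_grid()] (columns tau, auc).
#' @param horizon upper integration limit in months.
#' @return scalar iAU-ROC.
#' @export
iauroc <- function(grid, horizon) {
  keep <- !is.na(grid$auc) & grid$tau <= horizon
  tau <- grid$tau[keep]; auc <- grid$auc[keep]
  if (length(tau) < 2)
    abort_als("iauroc: fewer than 2 defined grid points up to %s months",
              horizon)
  pracma::trapz(tau, auc) / (max(tau) - min(tau))
}

# per-rep cumulative event fraction matrix: rows = grid, cols = reps
sim_cumulative_reps <- function(sim, outcome, time_grid) {
  et <- vapply(sim$followups, function(fu) fu$event_times[, outcome],
               numeric(sim$n_reps)) # reps x patients
  et <- matrix(et, nrow = sim$n_reps)
  vapply(seq_len(sim$n_reps), function(r) {
    x <- et[r, ]
    vapply(time_grid, function(tau) mean(!is.na(x) & x <= tau), 0)
  }, numeric(length(time_grid)))
}

#' Observed vs simulated cumulative incidence curves
#'
#' The observed curve is the cumulative fraction of patients with the
#' event by each grid time; the simulated curve is the mean over
#' repetitions of the per-repetition cumulative fraction, with the
#' across-repetition standard deviation as spread.
#'
#' @inheritParams auroc_grid
#' @return data.frame (tau, observed, simulated, sim_sd).
#' @export
calibration_curves <- function(sim, labels, outcome,
                               time_grid = seq(0, 96, by = 3)) {
  lab <- labels[labels$outcome == outcome, ]
  observed <- vapply(time_grid, function(tau)
    mean(lab$status == 1 & lab$time <= tau), 0)
  reps <- sim_cumulative_reps(sim, outcome, time_grid)
  reps <- matrix(reps, nrow = length(time_grid))
  data.frame(tau = time_grid, observed = observed,
             simulated = rowMeans(reps),
             sim_sd = apply(reps, 1, sd))
}

#' Default calibration time slices
#'
#' The eight intervals (months since onset) used for the chi-squared
#' goodness-of-fit comparison of observed and simulated event counts.
#'
#' @return two-column matrix of interval bounds, intervals `(lo, hi]`
#'   except the first which is `[0, 6]`.
#' @export
default_slices <- function() {
  cbind(lo = c(0, 6, 9, 12, 18, 24, 30, 36),
        hi = c(6, 9, 12, 18, 24, 30, 36, 96))
}

slice_counts <- function(times, slices) {
  vapply(seq_len(nrow(slices)), function(i)
    sum(times > slices[i, 1] & times <= slices[i, 2]) +
      if (i == 1) sum(times == 0) else 0L, 0)
}

#' Chi-squared goodness of fit of simulated event counts
#'
#' Counts observed events per time slice and compares them with the
#' expected counts from the simulation. With `mode = "rep-mean"` the
#' expected count is the mean simulated event count per slice over
#' repetitions, scaled to the real cohort size; `"pooled"` pools events of
#' all repetitions and rescales. A slice with zero expected count but
#' positive observed count is merged with its upper neighbour (logged).
#'
#' @inheritParams auroc_grid
#' @param slices two-column matrix of interval bounds, default
#'   [default_slices()].
#' @param mode expected-count convention.
#' @return list(statistic, df, p_value, table) where `table` holds the
#'   per-slice observed and expected counts.
#' @export
calibration_chi2 <- function(sim, labels, outcome,
                             slices = default_slices(),
                             mode = c("rep-mean", "pooled")) {
  mode <- match.arg(mode)
  lab <- labels[labels$outcome == outcome, ]
  obs <- slice_counts(lab$time[lab$status == 1], slices)
  et <- vapply(sim$followups, function(fu) fu$event_times[, outcome],
               numeric(sim$n_reps))
  et <- matrix(et, nrow = sim$n_reps)
  n_real <- nrow(lab)
  n_sim <- ncol(et)
  scale <- n_real / n_sim
  if (mode == "rep-mean") {
    per_rep <- vapply(seq_len(sim$n_reps), function(r)
      slice_counts(et[r, !is.na(et[r, ])], slices), numeric(nrow(slices)))
    exp_counts <- rowMeans(matrix(per_rep, nrow = nrow(slices))) * scale
  } else {
    all_t <- et[!is.na(et)]
    exp_counts <- slice_counts(all_t, slices) * scale / sim$n_reps
  }
  tab <- data.frame(lo = slices[, 1], hi = slices[, 2],
                    observed = obs, expected = exp_counts)
  # merge empty-expected slices upward
  i <- 1
  while (i <= nrow(tab)) {
    if (tab$expected[i] == 0 && tab$observed[i] > 0) {
      j <- if (i < nrow(tab)) i + 1 else i - 1
      if (j < 1) break
      warn_als("calibration_chi2: merging slice (%g,%g] into its neighbour",
               tab$lo[i], tab$hi[i])
      tab$observed[j] <- tab$observed[j] + tab$observed[i]
      tab$expected[j] <- tab$expected[j] + tab$expected[i]
      tab$lo[j] <- min(tab$lo[i], tab$lo[j])
      tab$hi[j] <- max(tab$hi[i], tab$hi[j])
      tab <- tab[-i, , drop = FALSE]
    } else i <- i + 1
  }
  use <- tab$expected > 0
  stat <- sum((tab$observed[use] - tab$expected[use])^2 / tab$expected[use])
  df <- max(sum(use) - 1, 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab)
}

#' Full evaluation report for a simulated test cohort
#'
#' Per outcome: the AU-ROC grid (3-month steps), the integrated AU-ROC at
#' the requested horizons, the calibration curves and the chi-squared
#' goodness of fit on the default time slices.
#'
#' @param sim a `cohort_sim` of the test baselines.
#' @param labels observed labels from [extract_labels()].
#' @param time_grid AU-ROC evaluation grid, default 3-month steps 6..96.
#' @param horizons iAU-ROC horizons in months, default c(24, 36, 96).
#' @param slices calibration slices, default [default_slices()].
#' @param outcomes outcomes to evaluate, default all five.
#' @return an object of class `evaluation_report`.
#' @export
evaluate_model <- function(sim, labels, time_grid = seq(6, 96, by = 3),
                           horizons = c(24, 36, 96),
                           slices = default_slices(),
                           outcomes = SIM_OUTCOMES) {
  per_outcome <- lapply(outcomes, function(oc) {
    grid <- auroc_grid(sim, labels, oc, time_grid)
    ia <- vapply(horizons, function(h)
      tryCatch(iauroc(grid, h), error = function(e) NA_real_), 0)
    names(ia) <- paste0("h", horizons)
    chi2 <- calibration_chi2(sim, labels, oc, slices)
    calib <- calibration_curves(sim, labels, oc,
                                time_grid = seq(0, max(slices), by = 3))
    list(outcome = oc, auroc = grid, iauroc = ia, calibration = calib,
         chi2 = chi2)
  })
  names(per_outcome) <- outcomes
  structure(list(outcomes = per_outcome, horizons = horizons,
                 time_grid = time_grid,
                 n_patients = length(sim$patient_ids),
                 n_reps = sim$n_reps),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation report: %d patients x %d reps\n",
              x$n_patients, x$n_reps))
  for (oc in names(x$outcomes)) {
    ia <- x$outcomes[[oc]]$iauroc
    cat(sprintf("  %-20s iAU-ROC %s  chi2 p=%.3f\n", oc,
                paste(sprintf("%s=%.3f", names(ia), ia), collapse = " "),
                x$outcomes[[oc]]$chi2$p_value))
  }
  invisible(x)
}

#' Write / read an evaluation report as JSON
#' @param report an `evaluation_report`.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  x <- list(horizons = report$horizons, time_grid = report$time_grid,
            n_patients = report$n_patients, n_reps = report$n_reps,
            outcomes = lapply(report$outcomes, function(oc)
              list(outcome = oc$outcome,
                   auroc = as.list(oc$auroc),
                   iauroc = as.list(oc$iauroc),
                   calibration = as.list(oc$calibration),
                   chi2 = list(statistic = oc$chi2$statistic,
                               df = oc$chi2$df, p_value = oc$chi2$p_value,
                               table = as.list(oc$chi2$table)))))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  outcomes <- lapply(x$outcomes, function(oc) {
    ia <- unlist(oc$iauroc)
    list(outcome = oc$outcome,
         auroc = as.data.frame(oc$auroc),
         iauroc = ia,
         calibration = as.data.frame(oc$calibration),
         chi2 = list(statistic = oc$chi2$statistic, df = oc$chi2$df,
                     p_value = oc$chi2$p_value,
                     table = as.data.frame(oc$chi2$table)))
  })
  structure(list(outcomes = outcomes, horizons = x$horizons,
                 time_grid = x$time_grid, n_patients = x$n_patients,
                 n_reps = x$n_reps),
            class = "evaluation_report")
}
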