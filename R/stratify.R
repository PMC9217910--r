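# Risk-factor stratification: split a cohort on a baseline variable,
# simulate each stratum, and compare event-time densities and cumulative
# risk curves.

#' Simulate strata defined by a baseline variable
#'
#' Splits the baseline rows into strata by the levels of `variable`
#' (optionally grouped), simulates each stratum with the model, and pools
#' all repetitions' event times per stratum. The event-time density is a
#' histogram with 1-month bins (mode = earliest argmax, since integer
#' months are reported); the cumulative risk curve at each grid time is
#' the fraction of all repetitions (patients x reps) with the event by
#' then.
#'
#' @param model a `two_slice_dbn`.
#' @param baselines data.frame of complete baseline rows.
#' @param variable baseline variable to stratify on.
#' @param outcome a MiToS flag name or `"death"`.
#' @param groups named list mapping stratum label to a character vector of
#'   levels; default: one stratum per observed level.
#' @param config a [sim_config()].
#' @param time_grid common grid for the cumulative curves (months).
#' @param include_baseline_impaired keep patients already impaired at
#'   baseline (their event time is the baseline tso); set FALSE to drop
#'   them.
#' @return list of class `strata_result`: per stratum `label`,
#'   `n_patients`, `times` (pooled event times), `density` (1-month
#'   histogram), `mode` (months), `cumulative` (data.frame tau/risk).
#'   Empty strata are reported with `n_patients = 0` and NULL summaries.
#' @export
stratify_and_simulate <- function(model, baselines, variable, outcome,
                                  groups = NULL, config = sim_config(),
                                  time_grid = seq(0, 120, by = 1),
                                  include_baseline_impaired = TRUE) {
  if (!variable %in% names(baselines))
    abort_als("variable '%s' not present in baselines", variable)
  if (is.null(groups)) {
    lv <- unique(as.character(baselines[[variable]]))
    lv <- lv[!is.na(lv)]
    groups <- as.list(setNames(lv, lv))
  }
  if (!include_baseline_impaired && outcome %in% names(baselines))
    baselines <- baselines[is.na(baselines[[outcome]]) |
                             baselines[[outcome]] != "1", , drop = FALSE]
  strata <- lapply(names(groups), function(label) {
    rows <- baselines[!is.na(baselines[[variable]]) &
                        baselines[[variable]] %in% groups[[label]], ,
                      drop = FALSE]
    if (nrow(rows) == 0)
      return(list(label = label, n_patients = 0L, times = numeric(0),
                  density = NULL, mode = NA_real_, cumulative = NULL))
    sim <- simulate_cohort(model, rows, config)
    times <- unlist(lapply(sim$followups, function(fu) {
      x <- fu$event_times[, outcome]
      x[!is.na(x)]
    }), use.names = FALSE)
    n_total <- nrow(rows) * config$n_reps
    cum <- data.frame(tau = time_grid,
                      risk = vapply(time_grid, function(tau)
                        sum(times <= tau) / n_total, 0))
    dens <- event_time_density(times)
    list(label = label, n_patients = nrow(rows), times = times,
         density = dens, mode = attr(dens, "mode"), cumulative = cum)
  })
  names(strata) <- names(groups)
  class(strata) <- "strata_result"
  strata
}

# 1-month histogram density of pooled event times; mode = earliest argmax
event_time_density <- function(times) {
  if (length(times) == 0) return(NULL)
  breaks <- seq(0, ceiling(max(times)) + 1, by = 1)
  h <- hist(times, breaks = breaks, plot = FALSE)
  out <- data.frame(month = h$mids, density = h$density,
                    count = h$counts)
  attr(out, "mode") <- h$mids[which.max(h$counts)] # first of ties
  out
}

#' Compare strata at a given time
#'
#' @param strata a `strata_result`.
#' @param at_time months since onset; must lie within the common grid.
#' @return data.frame (stratum, n_patients, cumulative_risk, mode_months).
#' @export
compare_strata <- function(strata, at_time) {
  rows <- lapply(strata, function(s) {
    risk <- if (is.null(s$cumulative)) NA_real_ else {
      if (at_time < min(s$cumulative$tau) || at_time > max(s$cumulative$tau))
        abort_als("at_time %.1f outside the common grid", at_time)
      s$cumulative$risk[max(which(s$cumulative$tau <= at_time))]
    }
    data.frame(stratum = s$label, n_patients = s$n_patients,
               cumulative_risk = risk, mode_months = s$mode)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Plot stratified event-time densities and cumulative curves
#'
#' Two-panel base-graphics plot: per-stratum event-time density on the
#' left, cumulative risk on the right.
#'
#' @param x a `strata_result`.
#' @param density_xlim x range of the density panel in months.
#' @param ... unused.
#' @export
plot.strata_result <- function(x, density_xlim = c(0, 60), ...) {
  ok <- Filter(function(s) s$n_patients > 0, x)
  if (length(ok) == 0) abort_als("nothing to plot: all strata empty")
  cols <- seq_along(ok) + 1
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  ymax <- max(unlist(lapply(ok, function(s) s$density$density)))
  plot(NA, xlim = density_xlim, ylim = c(0, ymax * 1.05),
       xlab = "months since onset", ylab = "density",
       main = "event-time density")
  for (i in seq_along(ok))
    lines(ok[[i]]$density$month, ok[[i]]$density$density, col = cols[i],
          lwd = 2)
  legend("topright", legend = vapply(ok, `[[`, "", "label"), col = cols,
         lwd = 2, bty = "n")
  plot(NA, xlim = range(ok[[1]]$cumulative$tau), ylim = c(0, 1),
       xlab = "months since onset", ylab = "cumulative probability",
       main = "cumulative risk")
  for (i in seq_along(ok))
    lines(ok[[i]]$cumulative$tau, ok[[i]]$cumulative$risk, col = cols[i],
          lwd = 2)
  invisible(x)
}

#' Plot observed vs simulated cumulative incidence
#'
#' @param calib data.frame from [calibration_curves()].
#' @param main plot title.
#' @export
plot_calibration <- function(calib, main = "calibration") {
  plot(calib$tau, calib$observed, type = "l", col = "darkorange", lwd = 2,
       ylim = c(0, 1), xlab = "months since onset",
       ylab = "cumulative probability", main = main)
  polygon(c(calib$tau, rev(calib$tau)),
          c(pmin(calib$simulated + calib$sim_sd, 1),
            rev(pmax(calib$simulated - calib$sim_sd, 0))),
          col = grDevices::adjustcolor("darkgreen", 0.2), border = NA)
  lines(calib$tau, calib$simulated, col = "darkgreen", lwd = 2)
  legend("bottomright", legend = c("observed", "simulated"),
         col = c("darkorange", "darkgreen"), lwd = 2, bty = "n")
  invisible(calib)
}
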