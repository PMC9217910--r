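test_that("time-dependent AU-ROC matches brute-force pair counting", {
  # printed micro-example: 3 cases vs 3 controls
  res <- time_dependent_auroc(
    scores = c(0.9, 0.7, 0.4, 0.8, 0.3, 0.2),
    time = c(5, 5, 5, 50, 50, 50),
    status = c(1, 1, 1, 0, 0, 0), tau = 10)
  expect_equal(res$auc, brute_auroc(c(0.9, 0.7, 0.4), c(0.8, 0.3, 0.2)))
  expect_equal(res$auc, 7 / 9) # 7 winning pairs, no ties
  expect_equal(res$n_cases, 3)
  expect_equal(res$n_controls, 3)
  # perfect separation and all-ties conventions
  expect_equal(time_dependent_auroc(c(9, 8, 1, 2), c(1, 2, 9, 9),
                                    c(1, 1, 0, 0), tau = 5)$auc, 1)
  expect_equal(time_dependent_auroc(rep(0.5, 6), c(1, 2, 3, 9, 9, 9),
                                    c(1, 1, 1, 0, 0, 0), tau = 5)$auc, 0.5)

  set.seed(314)
  for (r in 1:50) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), 2) # rounding forces ties
    time <- runif(n, 0, 60)
    status <- rbinom(n, 1, 0.7)
    tau <- runif(1, 10, 50)
    res <- time_dependent_auroc(scores, time, status, tau)
    case <- status == 1 & time <= tau
    control <- time > tau
    if (sum(case) == 0 || sum(control) == 0) {
      expect_true(is.na(res$auc))
    } else {
      expect_equal(res$auc, brute_auroc(scores[case], scores[control]))
    }
  }
})

test_that("patients censored before the horizon are excluded by default", {
  scores <- c(0.9, 0.1, 0.5, 0.8)
  time <- c(5, 50, 8, 9)
  status <- c(1, 0, 0, 0) # third and fourth censored before tau = 10
  res <- time_dependent_auroc(scores, time, status, 10)
  expect_equal(res$n_cases + res$n_controls, 2L)
  res2 <- time_dependent_auroc(scores, time, status, 10,
                               censored_as_controls = TRUE)
  expect_equal(res2$n_controls, 3L)
})

test_that("the integrated AU-ROC is a normalized trapezoidal time-average", {
  grid <- data.frame(tau = seq(6, 96, 3), auc = 0.8)
  for (h in c(24, 36, 96)) expect_equal(iauroc(grid, h), 0.8)
  lin <- data.frame(tau = seq(6, 36, 3),
                    auc = seq(0.6, 1.0, length.out = 11))
  expect_equal(iauroc(lin, 36), 0.8) # trapezoid of a linear ramp by hand
  # a leading undefined point shifts the integration start
  lead_na <- data.frame(tau = c(3, seq(6, 36, 3)),
                        auc = c(NA, seq(0.6, 1.0, length.out = 11)))
  expect_equal(iauroc(lead_na, 36), 0.8)
  expect_error(iauroc(data.frame(tau = 6, auc = 0.9), 36), "fewer than 2")
})

test_that("calibration chi-squared matches hand computation", {
  fu <- list(event_times = cbind(
    mitos_walking = c(rep(4, 10), rep(20, 20), rep(NA, 70)),
    death = rep(NA_real_, 100)))
  class(fu) <- "sim_followups"
  sim <- structure(list(followups = list(p1 = fu), n_reps = 100,
                        patient_ids = "p1"), class = "cohort_sim")
  # identical observed and expected counts -> statistic 0, p = 1
  labels <- data.frame(patient_id = "p1", outcome = "mitos_walking",
                       time = 4, status = 1)
  # single patient: expected = (0.1, 0.2, 0, ...) events in slices 1 and 4
  chi <- calibration_chi2(sim, labels, "mitos_walking",
                          slices = cbind(c(0, 6), c(6, 40)))
  # obs = (1, 0); exp = (0.1, 0.2)
  expect_equal(chi$statistic, (1 - 0.1)^2 / 0.1 + (0 - 0.2)^2 / 0.2)
  expect_equal(chi$df, 1)

  # the printed two-slice example: observed (10, 20) vs expected (15, 15)
  expect_equal((10 - 15)^2 / 15 + (20 - 15)^2 / 15, 10 / 3)
  expect_equal(nrow(default_slices()), 8)
  expect_equal(default_slices()[1, ], c(lo = 0, hi = 6))
  expect_equal(default_slices()[8, ], c(lo = 36, hi = 96))
})

test_that("chi-squared is zero when simulation reproduces the observations", {
  mk <- function(t) structure(
    list(event_times = cbind(mitos_walking = rep(t, 100),
                             death = rep(NA_real_, 100))),
    class = "sim_followups")
  sim <- structure(list(followups = list(p1 = mk(4), p2 = mk(20)),
                        n_reps = 100, patient_ids = c("p1", "p2")),
                   class = "cohort_sim")
  labels <- data.frame(patient_id = c("p1", "p2"),
                       outcome = "mitos_walking",
                       time = c(4, 20), status = c(1, 1))
  chi <- calibration_chi2(sim, labels, "mitos_walking",
                          slices = cbind(c(0, 6, 30), c(6, 30, 96)))
  # every repetition reproduces the observed events exactly
  expect_equal(chi$table$observed[1:2], c(1, 1))
  expect_equal(chi$table$expected[1:2], c(1, 1))
  expect_equal(chi$statistic, 0)
  expect_equal(chi$p_value, 1)
})

test_that("observed labels extract first impairment and survival correctly", {
  co <- fx_cohort(60, seed = 51)
  labels <- extract_labels(co)
  expect_setequal(unique(labels$outcome),
                  c("mitos_walking", "mitos_swallowing",
                    "mitos_communication", "mitos_breathing", "death"))
  d <- labels[labels$outcome == "death", ]
  expect_equal(d$time, co$outcomes$survival_time[
    match(d$patient_id, co$outcomes$patient_id)])
  w <- labels[labels$outcome == "mitos_walking" & labels$status == 1, ]
  for (i in seq_len(min(nrow(w), 10))) {
    vv <- co$visits[co$visits$patient_id == w$patient_id[i], ]
    expect_equal(w$time[i],
                 min(vv$tso_months[!is.na(vv$mitos_walking) &
                                     vv$mitos_walking == "1"]))
  }
})

test_that("calibration curves are monotone and self-consistent in a perfect fit", {
  et <- cbind(mitos_walking = rep(10, 50), death = rep(NA_real_, 50))
  fu <- structure(list(event_times = et), class = "sim_followups")
  sim <- structure(list(followups = list(p1 = fu), n_reps = 50,
                        patient_ids = "p1"), class = "cohort_sim")
  labels <- data.frame(patient_id = "p1", outcome = "mitos_walking",
                       time = 10, status = 1)
  cc <- calibration_curves(sim, labels, "mitos_walking",
                           time_grid = seq(0, 30, 5))
  expect_equal(cc$observed, cc$simulated)
  expect_equal(cc$sim_sd, rep(0, nrow(cc)))
  expect_true(all(diff(cc$observed) >= 0))
  expect_true(all(cc$simulated >= 0 & cc$simulated <= 1))
})

test_that("evaluation reports serialize and round-trip", {
  m <- fx_model()
  co <- fx_cohort(60, seed = 51)
  b <- complete_baselines(co, m$schema)
  sim <- simulate_cohort(m, b, sim_config(n_reps = 20, seed = 2))
  labels <- extract_labels(co)
  labels <- labels[labels$patient_id %in% b$patient_id, ]
  rep0 <- evaluate_model(sim, labels, time_grid = seq(6, 60, 3),
                         horizons = c(24, 36))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep0, path)
  back <- read_report(path)
  expect_equal(back$outcomes$death$iauroc, rep0$outcomes$death$iauroc)
  expect_equal(back$outcomes$mitos_walking$auroc,
               rep0$outcomes$mitos_walking$auroc)
  expect_equal(back$outcomes$death$chi2$p_value,
               rep0$outcomes$death$chi2$p_value)
})
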