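test_that("simulation is reproducible and independent of cohort ordering", {
  m <- fx_model()
  b <- complete_baselines(fx_cohort(), m$schema)[1:4, ]
  cfg <- sim_config(n_reps = 25, seed = 123)
  s1 <- simulate_cohort(m, b, cfg)
  s2 <- simulate_cohort(m, b[4:1, ], cfg)
  for (pid in s1$patient_ids)
    expect_identical(s1$followups[[pid]]$event_times,
                     s2$followups[[pid]]$event_times)
  s3 <- simulate_cohort(m, b, cfg)
  expect_identical(sim_events_table(s1), sim_events_table(s3))
})

test_that("sampled one-step frequencies match the stored tables", {
  m <- fx_model()
  b <- complete_baselines(fx_cohort(), m$schema)[2, , drop = FALSE]
  set.seed(9)
  draws <- simulate_step(m, b, n = 10000)
  for (child in c("mitos_walking", "mitos_breathing")) {
    cpt <- m$cpts[[child]]
    cfg <- vapply(cpt$parents, function(p)
      match(b[[p]], cpt$parent_levels[[p]]), 0L)
    p <- cpt$prob[alsdbn:::config_index(matrix(cfg, 1), cpt$parent_card), 2]
    phat <- mean(draws[[child]] == "1")
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 10000) + 1e-9)
  }
})

test_that("simulated levels stay within the declared level sets", {
  m <- fx_model()
  b <- complete_baselines(fx_cohort(), m$schema)[1, , drop = FALSE]
  fu <- simulate_patient(m, b, sim_config(n_reps = 10, max_steps = 15,
                                          seed = 2, record_states = TRUE))
  for (nm in c("mitos_walking", "tso", "tbv", "onset_site"))
    expect_true(all(fu$states[[nm]] %in%
                      alsdbn:::var_levels(m$schema, nm, as_parent = TRUE)))
  expect_true(all(fu$states$step <= 15))
})

test_that("death is absorbing: no outcome event follows a death", {
  m <- fx_model()
  b <- complete_baselines(fx_cohort(), m$schema)[1:5, ]
  sim <- simulate_cohort(m, b, sim_config(n_reps = 50, seed = 6))
  for (fu in sim$followups) {
    et <- fu$event_times
    dead <- !is.na(et[, "death"])
    for (oc in setdiff(colnames(et), "death"))
      expect_true(all(et[dead, oc] <= et[dead, "death"] + 1e-9,
                      na.rm = TRUE))
  }
})

test_that("baseline impairment pins the event time to the baseline tso", {
  m <- fx_model()
  b <- complete_baselines(fx_cohort(), m$schema)[1, , drop = FALSE]
  b$mitos_walking <- "1"
  fu <- simulate_patient(m, b, sim_config(n_reps = 20, seed = 3))
  expect_true(all(fu$event_times[, "mitos_walking"] == b$tso_months))
})

test_that("incomplete baselines are rejected with the variables named", {
  m <- fx_model()
  b <- complete_baselines(fx_cohort(), m$schema)[1, , drop = FALSE]
  b$mitos_breathing <- NA_character_
  expect_error(simulate_patient(m, b, sim_config(n_reps = 2)),
               "mitos_breathing")
})

test_that("risk curves count repetitions cumulatively", {
  fu <- list(event_times = cbind(
    mitos_walking = c(rep(10, 30), rep(20, 40), rep(NA, 30)),
    death = rep(NA_real_, 100)))
  class(fu) <- "sim_followups"
  expect_equal(risk_curve(fu, "mitos_walking", c(5, 12, 25)),
               c(0, 0.30, 0.70))
  expect_equal(risk_curve(fu, "death", c(5, 12)), c(0, 0))
  r <- risk_curve(fu, "mitos_walking", 0:40)
  expect_true(all(diff(r) >= 0))
  expect_error(risk_curve(fu, "mitos_walking", c(10, 5)), "increasing")
})

test_that("degenerate hazards make every repetition fail at the first step", {
  spec <- recovery_spec()
  spec$hazards <- lapply(spec$hazards, function(h) rep(1, 3))
  spec$modifiers <- list()
  spec$death_hazard <- rep(1, 3)
  spec$death_modifier <- NULL
  spec$persist <- 1
  m <- make_ground_truth(spec, seed = 1)
  b <- complete_baselines(fx_cohort(), m$schema)[1, , drop = FALSE]
  b[c("mitos_walking", "mitos_swallowing", "mitos_communication",
      "mitos_breathing")] <- "0"
  fu <- simulate_patient(m, b, sim_config(n_reps = 40, seed = 8))
  expect_true(all(fu$terminated_by == "death"))
  expect_true(all(fu$event_times[, "death"] > b$tso_months))
  # unit hazards: all four domains fail together at the first visit
  et <- fu$event_times
  for (fl in c("mitos_swallowing", "mitos_communication", "mitos_breathing"))
    expect_equal(et[, fl], et[, "mitos_walking"])
  expect_true(all(et[, "death"] >= et[, "mitos_walking"]))
})
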