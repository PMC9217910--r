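trajectory_cohort <- function(n_visits = c(p1 = 5, p2 = 3, p3 = 1),
                              surv = c(p1 = 60, p2 = 60, p3 = 60),
                              event = c(p1 = 0, p2 = 0, p3 = 0)) {
  visits <- do.call(rbind, lapply(names(n_visits), function(p)
    data.frame(patient_id = p,
               visit_time = seq(6, by = 3.5, length.out = n_visits[[p]]),
               onset_site = "spinal", mitos_walking = "0",
               mitos_swallowing = "0", mitos_communication = "0",
               mitos_breathing = "0")))
  co <- als_cohort(visits, data.frame(patient_id = names(n_visits),
                                      survival_time = unname(surv),
                                      event = unname(event)))
  discretize_cohort(derive_temporal_vars(co), recovery_schema())
}

test_that("each consecutive visit pair yields one transition row", {
  td <- build_transition_dataset(trajectory_cohort(), recovery_schema())
  expect_equal(td$n, 4 + 2 + 0)
  expect_true(all(td$to$survival == "alive"))
})

test_that("deceased patients get one terminal dead transition", {
  td <- build_transition_dataset(
    trajectory_cohort(n_visits = c(p1 = 3), surv = c(p1 = 30),
                      event = c(p1 = 1)),
    recovery_schema())
  expect_equal(td$n, 2 + 1)
  expect_equal(sum(td$to$survival == "dead"), 1)
  dead <- which(td$to$survival == "dead")
  # gap of the terminal row = death time minus last visit time
  expect_equal(td$tbv_raw[dead], 30 - 13)
  expect_true(all(is.na(td$to$mitos_walking[dead])))
})

test_that("censored patients contribute no rows past their last visit", {
  td <- build_transition_dataset(
    trajectory_cohort(n_visits = c(p1 = 3), surv = c(p1 = 30),
                      event = c(p1 = 0)),
    recovery_schema())
  expect_equal(td$n, 2)
  expect_true(all(td$to$survival == "alive"))
})

test_that("patients without visits are skipped with a warning", {
  co <- trajectory_cohort()
  co$outcomes <- rbind(co$outcomes,
                       data.frame(patient_id = "ghost", survival_time = 10,
                                  event = 0))
  expect_warning(td <- build_transition_dataset(co, recovery_schema()),
                 "without visits")
  expect_equal(td$n, 6)
})
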