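mini_cohort <- function(times = list(p1 = c(10, 13.5, 17), p2 = 8),
                        surv = c(p1 = 30, p2 = 12),
                        event = c(p1 = 1, p2 = 0)) {
  visits <- do.call(rbind, lapply(names(times), function(p)
    data.frame(patient_id = p, visit_time = times[[p]],
               mitos_walking = "0", mitos_swallowing = "0",
               mitos_communication = "0", mitos_breathing = "0",
               onset_site = "spinal")))
  als_cohort(visits, data.frame(patient_id = names(times),
                                survival_time = unname(surv[names(times)]),
                                event = unname(event[names(times)])))
}

test_that("temporal derivation computes tso and consecutive-visit gaps", {
  co <- derive_temporal_vars(mini_cohort())
  p1 <- co$visits[co$visits$patient_id == "p1", ]
  expect_equal(p1$tso_months, c(10, 13.5, 17))
  expect_equal(p1$tbv_months, c(NA, 3.5, 3.5))
  p2 <- co$visits[co$visits$patient_id == "p2", ]
  expect_equal(p2$tbv_months, NA_real_) # single visit: no predecessor
  expect_equal(p2$tso_months, 8)
})

test_that("unsorted visits produce the same derivation as sorted ones", {
  a <- derive_temporal_vars(mini_cohort(times = list(p1 = c(17, 10, 13.5))))
  b <- derive_temporal_vars(mini_cohort(times = list(p1 = c(10, 13.5, 17))))
  expect_identical(a$visits, b$visits)
})

test_that("invalid visit sequences are rejected with the patient named", {
  expect_error(derive_temporal_vars(mini_cohort(times = list(p1 = c(10, 10, 17)))),
               "p1.*duplicated visit times")
  expect_error(derive_temporal_vars(mini_cohort(times = list(p1 = c(-2, 5)))),
               "negative")
  expect_error(
    derive_temporal_vars(mini_cohort(times = list(p1 = c(10, 40)),
                                     surv = c(p1 = 20), event = c(p1 = 1))),
    "survival_time")
})

test_that("cohort CSV round-trip preserves visit content", {
  spec <- recovery_spec()
  co <- derive_temporal_vars(sample_cohort(fx_truth(), 40, spec, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- derive_temporal_vars(read_cohort_csv(path))
  for (col in c("patient_id", "visit_time", "onset_site", "mitos_walking",
                "tso_months", "tbv_months"))
    expect_equal(back$visits[[col]], co$visits[[col]])
  expect_equal(back$outcomes$survival_time, co$outcomes$survival_time)
  expect_equal(back$outcomes$event, co$outcomes$event)
})

test_that("discretization adds tso/tbv levels with the baseline marker", {
  spec <- recovery_spec()
  co <- discretize_cohort(
    derive_temporal_vars(sample_cohort(fx_truth(), 30, spec, seed = 6)),
    spec$schema)
  first <- !duplicated(co$visits$patient_id)
  expect_true(all(co$visits$tbv[first] == "baseline"))
  expect_true(all(co$visits$tbv[!first] %in%
                    c("tbv_short", "tbv_medium", "tbv_long")))
  expect_true(all(co$visits$tso %in% c("tso_early", "tso_mid", "tso_late")))
})
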