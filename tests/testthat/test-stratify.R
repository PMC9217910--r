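test_that("strata follow the grouping and degenerate to plain simulation", {
  m <- fx_model()
  b <- complete_baselines(fx_cohort(), m$schema)[1:20, ]
  cfg <- sim_config(n_reps = 20, seed = 9)
  strata <- stratify_and_simulate(m, b, "onset_site", "mitos_swallowing",
                                  config = cfg)
  expect_setequal(names(strata), unique(b$onset_site))
  expect_equal(sum(vapply(strata, `[[`, 0L, "n_patients")), nrow(b))
  # single-level variable: one stratum, identical to plain simulation
  b2 <- b; b2$onset_site <- "spinal"
  s1 <- stratify_and_simulate(m, b2, "onset_site", "mitos_swallowing",
                              config = cfg)
  expect_length(s1, 1)
  plain <- simulate_cohort(m, b2, cfg)
  pooled <- sort(unlist(lapply(plain$followups, function(fu) {
    x <- fu$event_times[, "mitos_swallowing"]; x[!is.na(x)]
  }), use.names = FALSE))
  expect_equal(sort(s1[[1]]$times), pooled)
})

test_that("the union of strata equals the plain cohort simulation", {
  m <- fx_model()
  b <- complete_baselines(fx_cohort(), m$schema)[1:16, ]
  cfg <- sim_config(n_reps = 15, seed = 4)
  strata <- stratify_and_simulate(m, b, "onset_site", "death", config = cfg)
  plain <- simulate_cohort(m, b, cfg)
  pooled <- sort(unlist(lapply(plain$followups, function(fu) {
    x <- fu$event_times[, "death"]; x[!is.na(x)]
  }), use.names = FALSE))
  expect_equal(sort(unlist(lapply(strata, `[[`, "times"),
                           use.names = FALSE)), pooled)
})

test_that("density mode equals the histogram argmax and curves are monotone", {
  m <- fx_model()
  b <- complete_baselines(fx_cohort(), m$schema)[1:15, ]
  strata <- stratify_and_simulate(m, b, "onset_site", "mitos_walking",
                                  config = sim_config(n_reps = 25, seed = 2))
  for (s in strata) {
    if (s$n_patients == 0) next
    h <- hist(s$times, breaks = seq(0, ceiling(max(s$times)) + 1, 1),
              plot = FALSE)
    expect_equal(s$mode, h$mids[which.max(h$counts)])
    expect_true(s$mode >= min(s$times) && s$mode <= max(s$times))
    expect_true(all(diff(s$cumulative$risk) >= 0))
    expect_true(all(s$cumulative$risk >= 0 & s$cumulative$risk <= 1))
  }
  tab <- compare_strata(strata, at_time = 40)
  expect_equal(nrow(tab), length(strata))
  expect_error(compare_strata(strata, at_time = 1e5), "outside")
})

test_that("already-impaired baselines can be excluded on request", {
  m <- fx_model()
  b <- complete_baselines(fx_cohort(), m$schema)[1:30, ]
  b$mitos_walking[1:10] <- "1"
  cfg <- sim_config(n_reps = 5, seed = 1)
  incl <- stratify_and_simulate(m, b, "onset_site", "mitos_walking",
                                config = cfg)
  excl <- stratify_and_simulate(m, b, "onset_site", "mitos_walking",
                                config = cfg,
                                include_baseline_impaired = FALSE)
  expect_equal(sum(vapply(incl, `[[`, 0L, "n_patients")), 30L)
  expect_equal(sum(vapply(excl, `[[`, 0L, "n_patients")),
               sum(b$mitos_walking != "1"))
})
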