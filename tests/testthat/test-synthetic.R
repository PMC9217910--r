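test_that("ground-truth construction is deterministic and satisfies its own invariants", {
  spec <- recovery_spec()
  m1 <- make_ground_truth(spec, seed = 33)
  m2 <- make_ground_truth(spec, seed = 33)
  expect_identical(m1$cpts, m2$cpts)
  expect_identical(m1$tbv$pools, m2$tbv$pools)
  # construction already runs the structural asserts; re-run explicitly
  expect_silent(alsdbn:::assert_structure(m1$structure, m1$schema,
                                          m1$constraints))
  # sharp spec: every transition-table row has a dominant entry
  for (nm in c(alsdbn:::MITOS_VARS, "survival", "tbv"))
    expect_true(all(apply(m1$cpts[[nm]]$prob, 1, max) >= 0.9))
  # monotone-tending impairment: persistence >= hazard everywhere
  for (fl in alsdbn:::MITOS_VARS) {
    cpt <- m1$cpts[[fl]]
    self <- match(fl, cpt$parents)
    cfg <- expand.grid(lapply(cpt$parent_card, seq_len))
    p1 <- cpt$prob[, 2]
    for (i in which(cfg[, self] == 1)) {
      twin <- cfg[i, ]; twin[self] <- 2
      j <- alsdbn:::config_index(as.matrix(twin), cpt$parent_card)
      expect_gte(p1[j], p1[i])
    }
  }
})

test_that("sampled cohorts have the requested size and registry-like shape", {
  spec <- ground_truth_spec()
  co <- derive_temporal_vars(sample_cohort(fx_basic_truth(), 500, spec,
                                           seed = 44))
  expect_equal(n_patients(co), 500)
  expect_equal(sort(unique(co$visits$patient_id)),
               sort(co$outcomes$patient_id))
  vpp <- table(co$visits$patient_id)
  expect_gt(mean(vpp), 3); expect_lt(mean(vpp), 9)
  expect_gt(mean(co$visits$tbv_months, na.rm = TRUE), 2.5)
  expect_lt(mean(co$visits$tbv_months, na.rm = TRUE), 4.5)
  # survival consistency: no visit after the survival time
  m <- merge(co$visits, co$outcomes, by = "patient_id")
  expect_true(all(m$visit_time <= m$survival_time + 1e-9))
  # censoring within a broad band of the nominal rate (administrative
  # censoring plus end-of-window truncation)
  cens <- mean(co$outcomes$event == 0)
  expect_gt(cens, spec$censor_rate - 0.05)
  expect_lt(cens, spec$censor_rate + 0.15)
})

test_that("sampling is deterministic in the seed", {
  spec <- recovery_spec()
  c1 <- sample_cohort(fx_truth(), 50, spec, seed = 7)
  c2 <- sample_cohort(fx_truth(), 50, spec, seed = 7)
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$outcomes, c2$outcomes)
})

test_that("realized missingness matches the requested MCAR rate", {
  spec <- recovery_spec()
  spec$missing_rate <- 0.1
  m <- make_ground_truth(spec, seed = 2)
  co <- sample_cohort(m, 2500, spec, seed = 3)
  cells <- unlist(co$visits[c("onset_site", alsdbn:::MITOS_VARS)])
  expect_gt(length(cells), 10000)
  expect_lt(abs(mean(is.na(cells)) - 0.1), 0.02)
})

test_that("empirical transition frequencies match the generating tables", {
  spec <- recovery_spec(); spec$missing_rate <- 0
  m <- make_ground_truth(spec, seed = 5)
  co <- discretize_cohort(
    derive_temporal_vars(sample_cohort(m, 8000, spec, seed = 6)),
    spec$schema)
  td <- build_transition_dataset(co, spec$schema)
  cpt <- m$cpts$mitos_walking
  fv <- alsdbn:::family_view(td, spec$schema, "mitos_walking", cpt$parents)
  counts <- alsdbn:::family_counts(fv)
  for (i in seq_len(nrow(counts))) {
    n <- sum(counts[i, ])
    if (n < 200) next
    p <- cpt$prob[i, 2]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(counts[i, 2] / n - p), 3 * se + 1e-9)
  }
})
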