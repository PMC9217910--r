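test_that("BIC of a parentless binary family matches the closed form", {
  td <- fake_tdata(from = data.frame(mitos_walking = rep("0", 100)),
                   to = data.frame(survival = rep(c("alive", "dead"), 50)))
  # 50/50 over 100 complete rows: ll = 100 ln(1/2), penalty = ln(100)/2
  expect_equal(family_bic(td, recovery_schema(), "survival"),
               100 * log(0.5) - 0.5 * log(100) * 1)
})

test_that("an informative parent raises BIC, an independent parent lowers it", {
  set.seed(99)
  sch <- recovery_schema()
  lower <- informative <- logical(20)
  for (r in 1:20) {
    n <- 5000
    a <- sample(c("0", "1"), n, replace = TRUE)
    b <- ifelse(runif(n) < 0.9, a, sample(c("0", "1"), n, replace = TRUE))
    noise <- sample(c("bulbar", "spinal"), n, replace = TRUE)
    td <- fake_tdata(from = data.frame(mitos_walking = a,
                                       onset_site = noise),
                     to = data.frame(mitos_swallowing = b))
    base <- family_bic(td, sch, "mitos_swallowing")
    lower[r] <- family_bic(td, sch, "mitos_swallowing",
                           c("mitos_walking", "onset_site")) <
      family_bic(td, sch, "mitos_swallowing", "mitos_walking")
    informative[r] <- family_bic(td, sch, "mitos_swallowing",
                                 "mitos_walking") > base
  }
  expect_true(all(lower))
  expect_true(all(informative))
})

test_that("available-cases scoring matches complete-data scoring when nothing is missing", {
  co <- fx_cohort(200, seed = 41)
  sch <- recovery_schema()
  td <- build_transition_dataset(co, sch)
  # strip the death rows' structurally-missing children by scoring survival
  s1 <- family_bic(td, sch, "survival", c("tso", "mitos_breathing"))
  td2 <- td
  keep <- stats::complete.cases(td$from[, c("tso", "mitos_breathing")]) &
    !is.na(td$to$survival)
  td2$from <- td$from[keep, , drop = FALSE]
  td2$to <- td$to[keep, , drop = FALSE]
  expect_equal(family_bic(td2, sch, "survival", c("tso", "mitos_breathing")),
               s1)
})

test_that("a family with no available cases scores -Inf with a warning", {
  td <- fake_tdata(from = data.frame(mitos_walking = rep(NA_character_, 10)),
                   to = data.frame(mitos_swallowing = rep("1", 10)))
  expect_warning(s <- family_bic(td, recovery_schema(), "mitos_swallowing",
                                 "mitos_walking"),
                 "no available cases")
  expect_identical(s, -Inf)
})
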