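test_that("a strong lag-one dependence is recovered across seeds", {
  sch <- recovery_schema()
  hits <- 0
  for (s in 1:10) {
    set.seed(1000 + s)
    n <- 5000
    a <- sample(c("0", "1"), n, replace = TRUE)
    b <- ifelse(runif(n) < 0.95, a, sample(c("0", "1"), n, replace = TRUE))
    td <- fake_tdata(from = data.frame(mitos_walking = a),
                     to = data.frame(mitos_swallowing = b))
    st <- mmhc_learn(td, sch, edge_constraints())
    hits <- hits +
      ("mitos_walking" %in% st$inter_parents$mitos_swallowing)
  }
  expect_gte(hits, 9)
})

test_that("forbidden edges are never added, mandatory edges never dropped", {
  sch <- recovery_schema()
  set.seed(77)
  n <- 3000
  a <- sample(c("0", "1"), n, replace = TRUE)
  b <- ifelse(runif(n) < 0.95, a, sample(c("0", "1"), n, replace = TRUE))
  td <- fake_tdata(from = data.frame(mitos_walking = a),
                   to = data.frame(mitos_swallowing = b))
  cons <- edge_constraints(
    forbidden = data.frame(parent = "mitos_walking",
                           child = "mitos_swallowing"))
  st <- mmhc_learn(td, sch, cons)
  expect_false("mitos_walking" %in% st$inter_parents$mitos_swallowing)

  cons2 <- edge_constraints(
    mandatory = data.frame(parent = "tso",
                           child = c("mitos_breathing", "survival")))
  st2 <- mmhc_learn(td, sch, cons2)
  expect_true("tso" %in% st2$inter_parents$mitos_breathing)
  expect_true("tso" %in% st2$inter_parents$survival)
})

test_that("with uninformative data only the mandatory edges remain", {
  sch <- recovery_schema()
  set.seed(5)
  td <- fake_tdata(
    from = data.frame(mitos_walking = sample(c("0", "1"), 60, TRUE)),
    to = data.frame(mitos_swallowing = sample(c("0", "1"), 60, TRUE)))
  cons <- default_constraints(sch)
  st <- mmhc_learn(td, sch, cons)
  edges <- alsdbn:::structure_edges(st)
  key <- paste(edges$parent, edges$child)
  mand <- paste(cons$mandatory$parent, cons$mandatory$child)
  expect_setequal(key, mand)
})

test_that("learned structures honour the layer rules on real synthetic data", {
  m <- fx_model()
  edges <- alsdbn:::structure_edges(m$structure)
  for (i in seq_len(nrow(edges)))
    expect_true(alsdbn:::edge_allowed(m$schema, m$constraints,
                                      edges$parent[i], edges$child[i]))
  # the returned structure scores at least as well as mandatory-only
  sch <- recovery_spec()$schema
  td <- build_transition_dataset(fx_cohort(), sch)
  cons <- default_constraints(sch)
  total_bic <- function(st) {
    sum(vapply(names(st$inter_parents), function(ch)
      family_bic(td, sch, ch, st$inter_parents[[ch]]), 0)) +
      sum(vapply(sch$static_names, function(ch)
        family_bic(td, sch, ch,
                   st$static_edges$parent[st$static_edges$child == ch]), 0))
  }
  mand_only <- list(
    static_edges = data.frame(parent = character(0), child = character(0)),
    inter_parents = lapply(setNames(nm = names(m$structure$inter_parents)),
                           function(ch)
                             alsdbn:::mandatory_parents(cons, ch)))
  expect_gte(total_bic(m$structure), total_bic(mand_only))
})

test_that("constraints forcing a static cycle are rejected before search", {
  sch <- basic_schema()
  cons <- edge_constraints(
    mandatory = data.frame(parent = c("onset_site", "diagnostic_delay"),
                           child = c("diagnostic_delay", "onset_site")))
  td <- build_transition_dataset(fx_basic_cohort(60, seed = 8), sch)
  expect_error(mmhc_learn(td, sch, cons), "cycle")
})
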