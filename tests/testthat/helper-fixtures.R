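# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# sharp 8-variable ground truth + discretized cohort sampled from it
fx_truth <- function() cached("truth", make_ground_truth(recovery_spec(), seed = 11))

fx_cohort <- function(n = 400, seed = 21) {
  cached(sprintf("cohort_%d_%d", n, seed), {
    spec <- recovery_spec()
    co <- derive_temporal_vars(sample_cohort(fx_truth(), n, spec, seed))
    discretize_cohort(co, spec$schema)
  })
}

fx_model <- function() {
  cached("model", {
    spec <- recovery_spec()
    td <- build_transition_dataset(fx_cohort(), spec$schema)
    st <- mmhc_learn(td, spec$schema)
    map_fit(td, spec$schema, st)
  })
}

# cohort over the full 11-variable basic schema
fx_basic_truth <- function()
  cached("basic_truth", make_ground_truth(ground_truth_spec(), seed = 19))

fx_basic_cohort <- function(n = 200, seed = 8) {
  cached(sprintf("basic_cohort_%d_%d", n, seed), {
    spec <- ground_truth_spec()
    co <- derive_temporal_vars(sample_cohort(fx_basic_truth(), n, spec, seed))
    discretize_cohort(co, spec$schema)
  })
}

complete_baselines <- function(cohort, schema) {
  b <- baseline_visits(cohort)
  b[stats::complete.cases(b[, alsdbn:::dbn_parents(schema), drop = FALSE]), ,
    drop = FALSE]
}

# O(n^2) brute-force cumulative/dynamic AU-ROC oracle with half ties:
# every case/control pair is enumerated and scored explicitly
brute_auroc <- function(case_scores, control_scores) {
  wins <- outer(case_scores, control_scores, ">")
  ties <- outer(case_scores, control_scores, "==")
  (sum(wins) + 0.5 * sum(ties)) /
    (length(case_scores) * length(control_scores))
}

# hand-rolled transition dataset over the 8-variable schema, for scoring
# and search tests with controlled dependences
fake_tdata <- function(from, to, schema = recovery_schema()) {
  pvars <- alsdbn:::dbn_parents(schema)
  cvars <- alsdbn:::dbn_children(schema)
  from$onset_site <- from$onset_site %||% "spinal"
  from$tbv <- from$tbv %||% "tbv_medium"
  from$tso <- from$tso %||% "tso_early"
  for (nm in setdiff(pvars, names(from))) from[[nm]] <- "0"
  to$survival <- to$survival %||% "alive"
  to$tbv <- to$tbv %||% "tbv_medium"
  for (nm in setdiff(cvars, names(to))) to[[nm]] <- "0"
  structure(list(from = from[, pvars, drop = FALSE],
                 to = to[, cvars, drop = FALSE],
                 tbv_raw = rep(3.5, nrow(from)),
                 baseline = data.frame(onset_site =
                   rep(c("bulbar", "spinal"), length.out = nrow(from))),
                 n = nrow(from)),
            class = "transition_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
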