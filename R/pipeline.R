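# End-to-end pipeline: ingest/synthesize -> derive -> discretize -> split
# -> learn -> simulate -> evaluate, with artifacts on disk.

#' Pipeline configuration
#'
#' @param out_dir output directory for artifacts.
#' @param seed master seed; every stage derives its own stream from it.
#' @param input path to a cohort CSV (see [read_cohort_csv()]); `NULL`
#'   generates a synthetic cohort instead.
#' @param synth_spec [ground_truth_spec()] used when `input` is NULL.
#' @param n_patients synthetic cohort size.
#' @param schema schema for ingested data; for synthetic runs the spec's
#'   schema is used.
#' @param ratio,n_attempts,alpha balanced-split settings (80:20 split
#'   scored over `n_attempts` draws at significance `alpha`).
#' @param mmhc MMHC parameters, see [mmhc_params()].
#' @param ess Dirichlet pseudo-count mass for MAP fitting.
#' @param sim simulation settings, see [sim_config()] (100 repetitions of
#'   up to 40 steps by default).
#' @param horizons iAU-ROC horizons in months.
#' @return a named list.
#' @export
pipeline_config <- function(out_dir = "als_run", seed = 1L, input = NULL,
                            synth_spec = ground_truth_spec(),
                            n_patients = 500L, schema = NULL,
                            ratio = 0.8, n_attempts = 50L, alpha = 0.01,
                            mmhc = mmhc_params(), ess = 1,
                            sim = sim_config(), horizons = c(24, 36, 96)) {
  list(out_dir = out_dir, seed = as.integer(seed), input = input,
       synth_spec = synth_spec, n_patients = as.integer(n_patients),
       schema = schema, ratio = ratio, n_attempts = as.integer(n_attempts),
       alpha = alpha, mmhc = mmhc, ess = ess, sim = sim,
       horizons = horizons)
}

#' Run the full modelling pipeline
#'
#' Executes ingest (or synthetic generation), temporal-variable
#' derivation, quantile-cut fitting on the training side, the balanced
#' 80:20 split, MMHC structure learning with MAP fitting, Monte-Carlo
#' simulation of every test baseline, and the full evaluation, writing
#' `cohort.csv`, `model.json`, `followups.csv`, `report.json` and
#' `split_report.csv` into `out_dir`. Every artifact records the master
#' seed and a configuration hash in its metadata; rerunning with the same
#' configuration reproduces them byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory objects (`cohort`, `split`,
#'   `model`, `sim`, `report`) and the artifact `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- sprintf("%08x",
                      derive_seed(0, paste(deparse(config[setdiff(
                        names(config), "out_dir")]), collapse = "")))

  if (is.null(config$input)) {
    spec <- config$synth_spec
    schema <- spec$schema
    truth <- make_ground_truth(spec, seed = derive_seed(config$seed, "truth"))
    cohort <- sample_cohort(truth, config$n_patients, spec,
                            seed = derive_seed(config$seed, "cohort"))
    say("stage synth: %d patients, %d visits", n_patients(cohort),
        nrow(cohort$visits))
  } else {
    schema <- config$schema %||% basic_schema()
    cohort <- read_cohort_csv(config$input)
    say("stage ingest: %d patients, %d visits", n_patients(cohort),
        nrow(cohort$visits))
  }
  cohort <- derive_temporal_vars(cohort)

  sp <- balanced_split(cohort, ratio = config$ratio,
                       n_attempts = config$n_attempts,
                       alpha = config$alpha,
                       seed = derive_seed(config$seed, "split"))
  say("stage split: %d train / %d test (min balance p = %.3f)",
      n_patients(sp$train), n_patients(sp$test),
      attr(sp$report, "min_p"))

  # quantile cuts frozen on the training side only
  schema <- fit_schema_cuts(schema, list(
    tso = sp$train$visits$tso_months,
    tbv = sp$train$visits$tbv_months))
  train <- discretize_cohort(sp$train, schema)
  test <- discretize_cohort(sp$test, schema)

  model <- learn_dbn(train, schema, params = config$mmhc, ess = config$ess)
  model$meta$seed <- config$seed
  model$meta$config_hash <- cfg_hash
  say("stage learn: %d transitions, %d families", model$meta$n_transitions,
      length(model$cpts))

  base <- baseline_visits(test)
  complete <- stats::complete.cases(base[, dbn_parents(schema),
                                         drop = FALSE])
  if (!all(complete))
    say("stage simulate: dropping %d incomplete baselines",
        sum(!complete))
  base <- base[complete, , drop = FALSE]
  sim_cfg <- config$sim
  sim_cfg$seed <- derive_seed(config$seed, "simulate")
  sim <- simulate_cohort(model, base, sim_cfg)
  say("stage simulate: %d patients x %d reps", length(sim$followups),
      sim$n_reps)

  labels <- extract_labels(test)
  labels <- labels[labels$patient_id %in% base$patient_id, ]
  report <- evaluate_model(sim, labels, horizons = config$horizons)

  paths <- list(
    cohort = file.path(config$out_dir, "cohort.csv"),
    model = file.path(config$out_dir, "model.json"),
    followups = file.path(config$out_dir, "followups.csv"),
    report = file.path(config$out_dir, "report.json"),
    split_report = file.path(config$out_dir, "split_report.csv"))
  write_cohort_csv(cohort, paths$cohort)
  write_dbn(model, paths$model)
  ev <- sim_events_table(sim)
  ev$seed <- config$seed; ev$config_hash <- cfg_hash
  write.csv(ev, paths$followups, row.names = FALSE, na = "")
  write_report(report, paths$report)
  rep_out <- sp$report
  rep_out$seed <- config$seed; rep_out$config_hash <- cfg_hash
  write.csv(rep_out, paths$split_report, row.names = FALSE)
  say("done: artifacts in %s", config$out_dir)
  invisible(list(cohort = cohort, split = sp, schema = schema,
                 model = model, sim = sim, report = report,
                 paths = paths))
}
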