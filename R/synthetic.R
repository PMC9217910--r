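# Ground-truth DBN generator and synthetic cohort sampler: every pipeline
# stage is testable without registry data, and in-silico populations can
# be produced at will. The cohorts emulate the structure of ALS clinic
# registries: a handful of visits per patient at a mean spacing of about
# 3.5 months, monotone-tending binary impairment flags, right-censored
# survival and per-variable missingness.

#' Specification of a synthetic ground-truth DBN
#'
#' All probabilities are per simulated visit (one DBN time step, about
#' 3.5 months on average under the default tbv distribution).
#'
#' @param schema a `cohort_schema`; default [basic_schema()].
#' @param static_edges data.frame (parent, child) over static variables.
#' @param inter_parents named list: slice-t child -> parents (statics and
#'   slice-(t-1) variables); must include the mandated tso edges.
#' @param static_probs named list of marginal probability vectors for
#'   root static variables (defaults to mildly non-uniform marginals).
#' @param sharpness target maximum row probability of the static
#'   conditional tables, in (1/levels, 1].
#' @param persist probability that an impaired MiToS domain stays
#'   impaired at the next visit (flags are monotone-tending, not strictly
#'   absorbing).
#' @param hazards named list: flag -> per-step impairment probability for
#'   each tso level (vector of length n tso levels).
#' @param modifiers named list: flag -> list of modifier specs, each a
#'   list(parent, level, factor, floor); when the parent takes the level,
#'   the hazard becomes `min(max(h * factor, floor), cap)`, applied in
#'   order. The defaults encode established clinical effects: bulbar
#'   onset accelerates swallowing and communication impairment.
#' @param death_hazard per-step death probability per tso level.
#' @param death_modifier like `modifiers`, applied to the death hazard;
#'   defaults encode respiratory impairment, older age at onset and
#'   bulbar onset as the standard adverse survival factors.
#' @param tbv_probs matrix (n tso levels x n tbv bins): distribution of
#'   the next inter-visit gap bin given the current tso level.
#' @param tbv_lnorm c(meanlog, sdlog) of the log-normal inter-visit gap
#'   distribution feeding the per-bin empirical pools (mean about 3.5
#'   months under the default).
#' @param censor_rate probability of administrative censoring before
#'   death.
#' @param missing_rate per-cell missing-completely-at-random rate applied
#'   to static and dynamic values (never to ids, visit times or survival).
#' @param max_visits maximum number of recorded visits per patient.
#' @param baseline list: `tso0_meanlog`, `tso0_sdlog` (log-normal time
#'   from onset to first visit) and `impair_p` (named per-flag probability
#'   of already being impaired at the first visit).
#' @return a named list of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(
    schema = basic_schema(),
    static_edges = NULL,
    inter_parents = NULL,
    static_probs = NULL,
    sharpness = 0.8,
    persist = 0.97,
    hazards = list(mitos_walking = c(0.06, 0.12, 0.20),
                   mitos_swallowing = c(0.03, 0.07, 0.13),
                   mitos_communication = c(0.02, 0.05, 0.10),
                   mitos_breathing = c(0.03, 0.07, 0.14)),
    modifiers = list(
      mitos_swallowing = list(
        list(parent = "onset_site", level = "bulbar", factor = 2.5,
             floor = 0)),
      mitos_communication = list(
        list(parent = "mitos_walking", level = "1", factor = 2.0,
             floor = 0),
        list(parent = "onset_site", level = "bulbar", factor = 2.0,
             floor = 0))),
    death_hazard = c(0.05, 0.12, 0.25),
    death_modifier = list(
      list(parent = "mitos_breathing", level = "1", factor = 2.5,
           floor = 0),
      list(parent = "age_onset", level = "old", factor = 1.9, floor = 0),
      list(parent = "age_onset", level = "young", factor = 0.55,
           floor = 0),
      list(parent = "onset_site", level = "bulbar", factor = 1.5,
           floor = 0)),
    tbv_probs = rbind(c(0.50, 0.35, 0.15),
                      c(0.40, 0.35, 0.25),
                      c(0.35, 0.35, 0.30)),
    tbv_lnorm = c(meanlog = log(3.0), sdlog = 0.55),
    censor_rate = 0.2,
    missing_rate = 0.03,
    max_visits = 15L,
    baseline = list(tso0_meanlog = log(10), tso0_sdlog = 0.5,
                    impair_p = c(mitos_walking = 0.12,
                                 mitos_swallowing = 0.05,
                                 mitos_communication = 0.03,
                                 mitos_breathing = 0.05))) {
  if (is.null(static_edges)) {
    static_edges <- if (all(c("sex", "onset_site") %in% schema$static_names))
      data.frame(parent = "sex", child = "onset_site")
    else data.frame(parent = character(0), child = character(0))
  }
  modifiers <- lapply(modifiers, normalize_modifiers)
  death_modifier <- normalize_modifiers(death_modifier)
  in_schema <- function(mods)
    Filter(function(m) m$parent %in% names(schema$variables), mods)
  modifiers <- lapply(modifiers, in_schema)
  death_modifier <- in_schema(death_modifier)
  if (is.null(inter_parents)) {
    inter_parents <- list(tbv = TSO_VAR)
    for (fl in MITOS_VARS) inter_parents[[fl]] <- sort(c(fl, TSO_VAR))
    for (fl in names(modifiers))
      for (m in modifiers[[fl]])
        inter_parents[[fl]] <- sort(union(inter_parents[[fl]], m$parent))
    surv_par <- TSO_VAR
    for (m in death_modifier) surv_par <- sort(union(surv_par, m$parent))
    inter_parents[[SURVIVAL_VAR]] <- surv_par
  }
  n_tso <- length(schema$variables[[TSO_VAR]]$levels)
  for (fl in MITOS_VARS)
    stopifnot(length(hazards[[fl]]) == n_tso)
  stopifnot(length(death_hazard) == n_tso,
            nrow(tbv_probs) == n_tso,
            ncol(tbv_probs) == length(schema$variables[[TBV_VAR]]$levels),
            sharpness > 1 / 2, sharpness <= 1,
            censor_rate >= 0, censor_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(schema = schema, static_edges = static_edges,
                 inter_parents = inter_parents,
                 static_probs = static_probs, sharpness = sharpness,
                 persist = persist, hazards = hazards,
                 modifiers = modifiers, death_hazard = death_hazard,
                 death_modifier = death_modifier, tbv_probs = tbv_probs,
                 tbv_lnorm = tbv_lnorm, censor_rate = censor_rate,
                 missing_rate = missing_rate,
                 max_visits = as.integer(max_visits), baseline = baseline),
            class = "ground_truth_spec")
}

#' Minimal 8-variable schema for ground-truth experiments
#'
#' One static variable (onset site) plus the four MiToS flags, survival,
#' tbv and tso: the smallest configuration exercising every code path.
#' @return a `cohort_schema`.
#' @export
recovery_schema <- function() {
  vars <- list(
    variable_spec("onset_site", "static", "categorical",
                  c("bulbar", "spinal")),
    flag_spec("mitos_walking"), flag_spec("mitos_swallowing"),
    flag_spec("mitos_communication"), flag_spec("mitos_breathing"),
    variable_spec("survival", "outcome", "categorical", c("alive", "dead")),
    variable_spec("tbv", "derived-temporal", "discretized-continuous",
                  c("tbv_short", "tbv_medium", "tbv_long"), c(2.5, 4.5),
                  units = "months"),
    variable_spec("tso", "derived-temporal", "discretized-continuous",
                  c("tso_early", "tso_mid", "tso_late"), c(18, 36),
                  units = "months"))
  cohort_schema(vars, scenario = "custom")
}

#' Sharp-parameter spec over the 8-variable schema
#'
#' Every conditional-table row has maximum probability at least 0.9, so
#' the dependence structure is strongly identifiable; used for structure
#' and parameter recovery experiments.
#' @return a `ground_truth_spec`.
#' @export
recovery_spec <- function() {
  ground_truth_spec(
    schema = recovery_schema(),
    sharpness = 0.9,
    hazards = list(mitos_walking = c(0.03, 0.08, 0.92),
                   mitos_swallowing = c(0.02, 0.05, 0.90),
                   mitos_communication = c(0.02, 0.05, 0.90),
                   mitos_breathing = c(0.03, 0.08, 0.92)),
    modifiers = list(
      mitos_swallowing = list(parent = "onset_site", level = "bulbar",
                              factor = 1, floor = 0.90),
      mitos_communication = list(parent = "mitos_walking", level = "1",
                                 factor = 1, floor = 0.90)),
    death_hazard = c(0.02, 0.06, 0.90),
    death_modifier = list(parent = "mitos_breathing", level = "1",
                          factor = 1, floor = 0.90),
    tbv_probs = rbind(c(0.90, 0.05, 0.05),
                      c(0.05, 0.90, 0.05),
                      c(0.05, 0.05, 0.90)),
    censor_rate = 0, missing_rate = 0.05, max_visits = 4L)
}

# generic CPT assembly: prob_fn(named character config) -> prob vector
build_cpt <- function(schema, child, parents, prob_fn) {
  parents <- sort(parents)
  as_parent <- !(child %in% schema$static_names)
  parent_levels <- lapply(parents, function(p)
    var_levels(schema, p, as_parent = as_parent))
  names(parent_levels) <- parents
  child_levels <- var_levels(schema, child, as_parent = FALSE)
  configs <- if (length(parents) == 0) data.frame(row.names = 1) else
    expand.grid(parent_levels, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  prob <- t(vapply(seq_len(nrow(configs)), function(i) {
    cfg <- if (length(parents) == 0) character(0) else
      setNames(as.character(unlist(configs[i, ])), parents)
    p <- prob_fn(cfg)
    p / sum(p)
  }, numeric(length(child_levels))))
  list(child = child, parents = parents, child_levels = child_levels,
       parent_levels = parent_levels,
       parent_card = vapply(parent_levels, length, 0L),
       prob = prob, n_avail = NA_integer_, ess = 0)
}

# scale a row shape so its maximum equals `s`
sharpen <- function(row, s) {
  k <- which.max(row)
  out <- row
  out[-k] <- (1 - s) * row[-k] / sum(row[-k])
  out[k] <- s
  out
}

# wrap a bare modifier spec into a one-element list
normalize_modifiers <- function(mods) {
  if (is.null(mods) || length(mods) == 0) return(list())
  if (!is.null(mods$parent)) list(mods) else mods
}

apply_modifiers <- function(h, cfg, mods, cap) {
  for (mod in mods)
    if (mod$parent %in% names(cfg) && cfg[[mod$parent]] == mod$level)
      h <- max(h * mod$factor, mod$floor)
  min(h, cap)
}

#' Build a fully parameterized ground-truth DBN
#'
#' Constructs a `two_slice_dbn` from a [ground_truth_spec()]: static
#' tables at the requested sharpness, MiToS impairment tables from the
#' per-tso hazard profiles (with persistence `persist` once impaired, so
#' staying impaired is always at least as likely as becoming impaired),
#' the survival table from the death hazards, and the tbv table plus
#' log-normal empirical pools. Deterministic given spec and seed.
#'
#' @param spec a `ground_truth_spec`.
#' @param seed integer seed (drives the tbv pool draws).
#' @return a `two_slice_dbn` honouring the default constraint set.
#' @export
make_ground_truth <- function(spec, seed = 1L) {
  schema <- spec$schema
  cap <- spec$persist
  cpts <- list()

  # static layer: roots get stated or default marginals, children get
  # rotating-peak rows at the requested sharpness
  defaults <- list(sex = c(0.44, 0.56), onset_site = c(0.3, 0.7),
                   centre = c(0.45, 0.3, 0.25))
  for (v in schema$static_names) {
    par <- spec$static_edges$parent[spec$static_edges$child == v]
    lv <- var_levels(schema, v)
    if (length(par) == 0) {
      p <- spec$static_probs[[v]] %||% defaults[[v]] %||%
        sharpen(rep(1, length(lv)) + 0.1 * seq_along(lv), 0.5)
      cpts[[v]] <- build_cpt(schema, v, character(0), function(cfg) p)
    } else {
      r <- length(lv)
      counter <- new.env(); counter$i <- 0L
      cpts[[v]] <- build_cpt(schema, v, par, function(cfg) {
        counter$i <- counter$i + 1L
        peak <- (counter$i - 1L) %% r + 1L
        row <- rep((1 - spec$sharpness) / (r - 1), r)
        row[peak] <- spec$sharpness
        row
      })
    }
  }

  for (fl in MITOS_VARS) {
    h_tso <- spec$hazards[[fl]]
    mod <- normalize_modifiers(spec$modifiers[[fl]])
    cpts[[fl]] <- build_cpt(schema, fl, spec$inter_parents[[fl]],
      function(cfg) {
        tso_lvl <- match(cfg[[TSO_VAR]], var_levels(schema, TSO_VAR))
        if (cfg[[fl]] == "1") {
          p1 <- spec$persist
        } else {
          p1 <- apply_modifiers(h_tso[tso_lvl], cfg, mod, cap)
        }
        c(1 - p1, p1)
      })
  }

  cpts[[SURVIVAL_VAR]] <- build_cpt(schema, SURVIVAL_VAR,
    spec$inter_parents[[SURVIVAL_VAR]], function(cfg) {
      tso_lvl <- match(cfg[[TSO_VAR]], var_levels(schema, TSO_VAR))
      d <- apply_modifiers(spec$death_hazard[tso_lvl], cfg,
                           normalize_modifiers(spec$death_modifier), 0.97)
      c(1 - d, d)
    })

  cpts[[TBV_VAR]] <- build_cpt(schema, TBV_VAR, spec$inter_parents[[TBV_VAR]],
    function(cfg) {
      tso_lvl <- match(cfg[[TSO_VAR]], var_levels(schema, TSO_VAR))
      spec$tbv_probs[tso_lvl, ]
    })

  # log-normal inter-visit gap pools per bin
  set.seed(derive_seed(seed, "tbv-pools"))
  draws <- rlnorm(20000, spec$tbv_lnorm[[1]], spec$tbv_lnorm[[2]])
  tbv_spec <- schema$variables[[TBV_VAR]]
  bins <- cut_index(draws, tbv_spec$cuts)
  pools <- lapply(seq_along(tbv_spec$levels), function(b) {
    x <- sort(draws[bins == b])
    if (length(x) > 500)
      x <- unname(quantile(x, seq(0, 1, length.out = 500), type = 7))
    x
  })
  names(pools) <- tbv_spec$levels
  bounds <- c(max(0.25, min(draws)), tbv_spec$cuts, max(draws))

  st <- structure(list(static_edges = spec$static_edges,
                       inter_parents = spec$inter_parents),
                  class = "dbn_structure")
  model <- two_slice_dbn(schema, st, cpts,
                         tbv = list(mode = "bin-empirical", pools = pools,
                                    bounds = bounds),
                         constraints = default_constraints(schema),
                         meta = list(generator = "ground_truth",
                                     seed = seed))
  # monotone-tending invariant: staying impaired >= becoming impaired
  for (fl in MITOS_VARS) {
    cpt <- model$cpts[[fl]]
    self_col <- match(fl, cpt$parents)
    cfgs <- expand.grid(lapply(cpt$parent_card, seq_len))
    for (i in seq_len(nrow(cfgs))) {
      if (cfgs[i, self_col] != 2) next
      twin <- cfgs[i, ]; twin[self_col] <- 1
      j <- config_index(as.matrix(twin), cpt$parent_card)
      if (cpt$prob[i, 2] < cpt$prob[j, 2] - 1e-12)
        abort_als("ground truth: impairment persistence below hazard for %s",
                  fl)
    }
  }
  model
}

#' Sample a synthetic cohort from a ground-truth DBN
#'
#' Statics are sampled from the static layer, the time of the first visit
#' from the spec's baseline distribution, and visit sequences are rolled
#' forward with the model's own transition machinery until simulated
#' death, administrative censoring or the visit cap. Death is recorded in
#' the survival outcome, never as a visit row. Missingness is applied
#' per cell, missing-completely-at-random, to static and dynamic values
#' only.
#'
#' @param model a `two_slice_dbn` from [make_ground_truth()].
#' @param n_patients cohort size.
#' @param spec the `ground_truth_spec` used to build the model.
#' @param seed integer seed.
#' @return an `als_cohort` with raw (underived) visit rows.
#' @export
sample_cohort <- function(model, n_patients, spec, seed = 1L) {
  stopifnot(n_patients >= 1)
  schema <- model$schema
  set.seed(derive_seed(seed, "synthetic-cohort"))
  n <- n_patients
  ids <- sprintf("P%05d", seq_len(n))
  pvars <- dbn_parents(schema)
  S <- matrix(1L, n, length(pvars), dimnames = list(NULL, pvars))

  # statics, in topological order of the static layer
  topo <- schema$static_names
  edges <- model$structure$static_edges
  ordv <- character(0)
  remaining <- topo
  while (length(remaining) > 0) {
    free <- remaining[vapply(remaining, function(v)
      !any(edges$child == v & edges$parent %in% remaining), TRUE)]
    ordv <- c(ordv, free)
    remaining <- setdiff(remaining, free)
  }
  for (v in ordv) {
    cpt <- model$cpts[[v]]
    cfg <- if (length(cpt$parents) == 0) rep(1L, n) else
      config_index(S[, cpt$parents, drop = FALSE], cpt$parent_card)
    S[, v] <- sample_rows(cpt$prob[cfg, , drop = FALSE])
  }

  tso0 <- rlnorm(n, spec$baseline$tso0_meanlog, spec$baseline$tso0_sdlog)
  S[, TSO_VAR] <- cut_index(tso0, schema$variables[[TSO_VAR]]$cuts)
  S[, TBV_VAR] <- length(schema$variables[[TBV_VAR]]$levels) + 1L # baseline
  for (fl in MITOS_VARS)
    S[, fl] <- 1L + rbinom(n, 1, spec$baseline$impair_p[[fl]])
  for (dv in setdiff(schema$dynamic_names, MITOS_VARS))
    S[, dv] <- 1L

  visit_rows <- list(decode_states(schema, S, tso0, rep(0L, n),
                                   alive = rep(TRUE, n)))
  visit_rows[[1]]$patient_id <- ids
  tso_cont <- tso0
  alive <- rep(TRUE, n)
  death_time <- rep(NA_real_, n)
  for (step in seq_len(spec$max_visits - 1L)) {
    act <- which(alive)
    if (length(act) == 0) break
    st <- step_states(model, S[act, , drop = FALSE], tso_cont[act],
                      model$tbv$mode)
    died <- st$dead
    death_time[act[died]] <- st$tso_cont[died]
    alive[act[died]] <- FALSE
    keep <- !died
    if (any(keep)) {
      ka <- act[keep]
      S[ka, ] <- st$S[keep, , drop = FALSE]
      tso_cont[ka] <- st$tso_cont[keep]
      vr <- decode_states(schema, S[ka, , drop = FALSE], tso_cont[ka],
                          rep(step, length(ka)), alive = rep(TRUE, length(ka)))
      vr$patient_id <- ids[ka]
      visit_rows[[length(visit_rows) + 1L]] <- vr
    }
  }
  # patients still alive after the visit cap die off-study or are lost;
  # they are censored at their last recorded visit
  surv_time <- ifelse(is.na(death_time), tso_cont, death_time)
  event <- as.integer(!is.na(death_time))

  # administrative censoring before death for a censor_rate fraction
  cens <- runif(n) < spec$censor_rate
  c_time <- tso0 + runif(n) * pmax(surv_time - tso0, 0)
  surv_time[cens] <- pmax(c_time[cens], tso0[cens])
  event[cens] <- 0L

  visits <- do.call(rbind, visit_rows)
  visits$visit_time <- visits$tso_months
  keep_cols <- c("patient_id", "visit_time", pvars)
  visits <- visits[, keep_cols, drop = FALSE]
  # drop discrete tbv/tso columns: they are re-derived downstream
  visits$tbv <- NULL; visits$tso <- NULL
  visits <- visits[visits$visit_time <=
                     surv_time[match(visits$patient_id, ids)] + 1e-9, ,
                   drop = FALSE]

  # missing-completely-at-random cell deletion
  if (spec$missing_rate > 0) {
    for (v in c(schema$static_names, schema$dynamic_names)) {
      mask <- runif(nrow(visits)) < spec$missing_rate
      visits[[v]][mask] <- NA_character_
    }
  }
  visits <- visits[order(visits$patient_id, visits$visit_time), ,
                   drop = FALSE]
  rownames(visits) <- NULL
  als_cohort(visits,
             data.frame(patient_id = ids, survival_time = surv_time,
                        event = event))
}
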