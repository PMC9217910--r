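# Cohort schema: declarative description of every modelled variable.
#
# Roles:
#   static           -- time-invariant (demographics), one value per patient
#   dynamic          -- evolves visit to visit (MiToS flags, NIV, PEG)
#   derived-temporal -- tbv / tso, computed from visit times
#   outcome          -- survival status (alive/dead, absorbing)

#' Declare one modelled variable
#'
#' @param name variable name (column name in visit tables).
#' @param role one of `"static"`, `"dynamic"`, `"derived-temporal"`,
#'   `"outcome"`.
#' @param kind `"categorical"` or `"discretized-continuous"`.
#' @param levels ordered character vector of level labels.
#' @param cuts strictly increasing numeric thresholds (raw units); empty for
#'   categorical variables. For discretized-continuous variables
#'   `length(levels) == length(cuts) + 1` must hold once cuts are set; cuts
#'   may be `NULL` at declaration time and fitted later from training data
#'   (see [fit_schema_cuts()]).
#' @param units free-text unit annotation.
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, role, kind, levels, cuts = numeric(0),
                          units = "") {
  role <- match.arg(role, c("static", "dynamic", "derived-temporal",
                            "outcome"))
  kind <- match.arg(kind, c("categorical", "discretized-continuous"))
  levels <- as.character(levels)
  if (anyDuplicated(levels))
    abort_als("variable '%s': level labels must be unique", name)
  cuts <- as.numeric(cuts)
  if (length(cuts) > 0) {
    if (is.unsorted(cuts, strictly = TRUE))
      abort_als("variable '%s': cuts must be strictly increasing", name)
    if (kind == "discretized-continuous" &&
        length(levels) != length(cuts) + 1L)
      abort_als("variable '%s': need length(levels) == length(cuts) + 1",
                name)
    if (kind == "categorical")
      abort_als("variable '%s': categorical variables take no cuts", name)
  }
  structure(list(name = name, role = role, kind = kind, levels = levels,
                 cuts = cuts, units = units),
            class = "variable_spec")
}

#' Assemble a cohort schema
#'
#' A schema lists every variable, partitions them by role, and carries the
#' MiToS threshold table used to derive domain impairment flags from
#' ALSFRS-R item scores. It must contain the four MiToS domain flags,
#' the survival status, and the two derived temporal variables tbv
#' (time between visits) and tso (time since onset).
#'
#' @param variables list of [variable_spec()] objects.
#' @param scenario label: `"basic"`, `"advanced"` or `"custom"`.
#' @param mitos_thresholds threshold table, see [default_mitos_thresholds()].
#' @return an object of class `cohort_schema`.
#' @export
cohort_schema <- function(variables, scenario = "custom",
                          mitos_thresholds = default_mitos_thresholds()) {
  nm <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(nm)) abort_als("duplicate variable names in schema")
  names(variables) <- nm
  required <- c(MITOS_VARS, SURVIVAL_VAR, TBV_VAR, TSO_VAR)
  missing <- setdiff(required, nm)
  if (length(missing) > 0)
    abort_als("schema is missing required variables: %s",
              paste(missing, collapse = ", "))
  roles <- vapply(variables, `[[`, "", "role")
  if (variables[[SURVIVAL_VAR]]$role != "outcome")
    abort_als("'survival' must have role 'outcome'")
  for (v in c(TBV_VAR, TSO_VAR))
    if (variables[[v]]$role != "derived-temporal")
      abort_als("'%s' must have role 'derived-temporal'", v)
  structure(list(scenario = scenario, variables = variables,
                 static_names = nm[roles == "static"],
                 dynamic_names = nm[roles == "dynamic"],
                 temporal_names = nm[roles == "derived-temporal"],
                 outcome_names = nm[roles == "outcome"],
                 mitos_thresholds = mitos_thresholds),
            class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat(sprintf("cohort schema ('%s'): %d variables\n", x$scenario,
              length(x$variables)))
  for (v in x$variables)
    cat(sprintf("  %-20s %-16s %s [%s]\n", v$name, v$role, v$kind,
                paste(v$levels, collapse = "/")))
  invisible(x)
}

# Level labels of a variable. When tbv is used as a parent (slice t-1) it
# carries the distinguished first-visit level "baseline" in addition to its
# duration bins, so baseline rows remain usable as simulation start states.
var_levels <- function(schema, name, as_parent = FALSE) {
  lv <- schema$variables[[name]]$levels
  if (as_parent && name == TBV_VAR) c(lv, TBV_BASELINE) else lv
}

# names of variables that receive a learned transition CPT (children at
# slice t). tso is excluded: it evolves deterministically as tso + tbv.
dbn_children <- function(schema) {
  c(TBV_VAR, schema$dynamic_names, schema$outcome_names)
}

# names usable as slice-(t-1) parents of dynamic children. survival is
# excluded: every observed transition starts from an alive state, so it is
# constant on the from side.
dbn_parents <- function(schema) {
  c(schema$static_names, schema$dynamic_names, TBV_VAR, TSO_VAR)
}

#' Default MiToS threshold table
#'
#' Maps ALSFRS-R item scores to loss of independence in the four MiToS
#' domains. Each domain lists the contributing items (columns named
#' `alsfrs_1` .. `alsfrs_12`), the per-item cut score at or below which the
#' item counts as lost, and the combination rule (`"OR"`: any lost item
#' impairs the domain; `"AND"`: all listed items must be lost). The table is
#' configuration, not code: pass a modified copy to [cohort_schema()] to
#' change the staging rule.
#'
#' Defaults: walking/self-care lost if walking (item 8) <= 1 OR
#' dressing/hygiene (item 6) <= 1; swallowing lost if swallowing (item 3)
#' <= 1; communication lost if speech (item 1) <= 1 AND handwriting
#' (item 4) <= 1; breathing lost if dyspnoea (item 10) <= 1 OR respiratory
#' insufficiency (item 12) <= 2.
#'
#' @return named list of per-domain rules.
#' @export
default_mitos_thresholds <- function() {
  list(
    mitos_walking = list(items = c("alsfrs_8", "alsfrs_6"),
                         cuts = c(1, 1), rule = "OR"),
    mitos_swallowing = list(items = "alsfrs_3", cuts = 1, rule = "OR"),
    mitos_communication = list(items = c("alsfrs_1", "alsfrs_4"),
                               cuts = c(1, 1), rule = "AND"),
    mitos_breathing = list(items = c("alsfrs_10", "alsfrs_12"),
                           cuts = c(1, 2), rule = "OR")
  )
}

flag_spec <- function(name)
  variable_spec(name, "dynamic", "categorical", c("0", "1"))

#' Shipped schema presets
#'
#' `basic_schema()` mirrors a population-registry scenario: five static
#' demographic variables (sex, onset site, age at onset, diagnostic delay,
#' medical centre), the four MiToS domain flags, survival, and the derived
#' temporal variables. `advanced_schema()` adds genetics, familial ALS,
#' frontotemporal dementia, premorbid and at-diagnosis BMI, FVC at
#' diagnosis, and NIV/PEG support interventions.
#'
#' Continuous variables default to 3 quantile levels; the shipped cuts are
#' placeholders refitted from training data by [fit_schema_cuts()] except
#' where noted (FVC ships the cuts 84/101 percent of predicted).
#'
#' @return a `cohort_schema`.
#' @export
basic_schema <- function() {
  vars <- list(
    variable_spec("sex", "static", "categorical", c("female", "male")),
    variable_spec("onset_site", "static", "categorical",
                  c("bulbar", "spinal")),
    variable_spec("age_onset", "static", "discretized-continuous",
                  c("young", "middle", "old"), c(57, 68), units = "years"),
    variable_spec("diagnostic_delay", "static", "discretized-continuous",
                  c("short", "medium", "long"), c(7, 14), units = "months"),
    variable_spec("centre", "static", "categorical",
                  c("centre_A", "centre_B", "centre_C")),
    flag_spec("mitos_walking"), flag_spec("mitos_swallowing"),
    flag_spec("mitos_communication"), flag_spec("mitos_breathing"),
    variable_spec("survival", "outcome", "categorical", c("alive", "dead")),
    variable_spec("tbv", "derived-temporal", "discretized-continuous",
                  c("tbv_short", "tbv_medium", "tbv_long"), c(2.5, 4.5),
                  units = "months"),
    variable_spec("tso", "derived-temporal", "discretized-continuous",
                  c("tso_early", "tso_mid", "tso_late"), c(18, 36),
                  units = "months")
  )
  cohort_schema(vars, scenario = "basic")
}

#' @rdname basic_schema
#' @export
advanced_schema <- function() {
  base <- basic_schema()
  extra <- list(
    variable_spec("genetics", "static", "categorical",
                  c("WT", "C9orf72", "SOD1", "TARDBP", "FUS")),
    variable_spec("familial", "static", "categorical", c("no", "yes")),
    variable_spec("ftd", "static", "categorical", c("no", "yes")),
    variable_spec("bmi_premorbid", "static", "discretized-continuous",
                  c("low", "normal", "high"), c(24, 28), units = "kg/m2"),
    variable_spec("bmi_diagnosis", "static", "discretized-continuous",
                  c("low", "normal", "high"), c(22, 26), units = "kg/m2"),
    variable_spec("fvc_diagnosis", "static", "discretized-continuous",
                  c("fvc_low", "fvc_mid", "fvc_high"), c(84, 101),
                  units = "% predicted"),
    variable_spec("niv", "dynamic", "categorical", c("no", "yes")),
    variable_spec("peg", "dynamic", "categorical", c("no", "yes"))
  )
  cohort_schema(c(base$variables, extra), scenario = "advanced",
                mitos_thresholds = base$mitos_thresholds)
}

schema_to_list <- function(schema) {
  list(scenario = schema$scenario,
       variables = lapply(unname(schema$variables), function(v)
         list(name = v$name, role = v$role, kind = v$kind,
              levels = as.list(v$levels), cuts = as.list(v$cuts),
              units = v$units)),
       mitos_thresholds = lapply(schema$mitos_thresholds, function(d)
         list(items = as.list(d$items), cuts = as.list(d$cuts),
              rule = d$rule)),
       quantile_type = 7L,
       interval_convention = "right-closed")
}

schema_from_list <- function(x) {
  vars <- lapply(x$variables, function(v)
    variable_spec(v$name, v$role, v$kind, unlist(v$levels),
                  as.numeric(unlist(v$cuts)), v$units %||% ""))
  thr <- lapply(x$mitos_thresholds, function(d)
    list(items = unlist(d$items), cuts = as.numeric(unlist(d$cuts)),
         rule = d$rule))
  cohort_schema(vars, scenario = x$scenario %||% "custom",
                mitos_thresholds = thr)
}

#' Read / write a schema as YAML
#'
#' The serialized schema records the discretization cuts, the quantile
#' definition and the interval convention, so that a model learned from it
#' is reproducible bit for bit.
#'
#' @param schema a `cohort_schema`.
#' @param path file path.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(schema_to_list(schema), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  schema_from_list(yaml::read_yaml(path))
}
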