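# The two-slice DBN model object and its JSON serialization.

#' Two-slice dynamic Bayesian network
#'
#' The model consists of a contemporaneous DAG over static variables, a
#' set of inter-slice families (each dynamic/outcome/tbv child at slice t
#' with parents among statics and any slice-(t-1) variable), one
#' conditional probability table per family, and the empirical pools used
#' to convert sampled tbv bins back to continuous months. tso carries no
#' table: it advances deterministically as tso(t) = tso(t-1) + tbv(t) and
#' is re-discretized for conditioning.
#'
#' @param schema a `cohort_schema`.
#' @param structure a `dbn_structure`.
#' @param cpts named list of conditional tables (one per static variable
#'   and per inter-slice child).
#' @param tbv list with `mode` (`"bin-empirical"` or `"bin-uniform"`),
#'   `pools` (per-bin numeric vectors) and `bounds` (bin boundary vector).
#' @param constraints the `edge_constraints` the model honours.
#' @param meta named list of fit metadata (ess, seeds, sizes, params).
#' @return an object of class `two_slice_dbn`.
#' @export
two_slice_dbn <- function(schema, structure, cpts, tbv,
                          constraints = default_constraints(schema),
                          meta = list()) {
  for (cpt in cpts) {
    rs <- rowSums(cpt$prob)
    if (any(abs(rs - 1) > 1e-12))
      abort_als("CPT for '%s': rows do not sum to 1", cpt$child)
  }
  model <- list(schema = schema, structure = structure, cpts = cpts,
                tbv = tbv, constraints = constraints, meta = meta)
  class(model) <- "two_slice_dbn"
  assert_structure(structure, schema, constraints)
  model
}

#' @export
print.two_slice_dbn <- function(x, ...) {
  cat(sprintf("two-slice DBN (%s scenario): %d families\n",
              x$schema$scenario, length(x$cpts)))
  print(x$structure)
  invisible(x)
}

#' Write / read a model as JSON
#'
#' The file contains the schema (with frozen discretization cuts), the
#' constraints, the structure, every conditional table at full precision,
#' the tbv pools and the fit metadata: everything needed to reproduce a
#' simulation bit for bit.
#'
#' @param model a `two_slice_dbn`.
#' @param path file path.
#' @export
write_dbn <- function(model, path) {
  cpt_list <- lapply(model$cpts, function(cpt)
    list(child = cpt$child, parents = as.list(cpt$parents),
         child_levels = as.list(cpt$child_levels),
         parent_levels = lapply(cpt$parent_levels, as.list),
         prob = apply(cpt$prob, 1, as.list, simplify = FALSE),
         n_avail = cpt$n_avail, ess = cpt$ess))
  x <- list(
    schema = schema_to_list(model$schema),
    constraints = list(
      mandatory = df_to_edges(model$constraints$mandatory),
      forbidden = df_to_edges(model$constraints$forbidden),
      no_parent_vars = as.list(model$constraints$no_parent_vars)),
    structure = list(
      static_edges = df_to_edges(model$structure$static_edges),
      inter_parents = lapply(model$structure$inter_parents, as.list)),
    cpts = cpt_list,
    tbv = list(mode = model$tbv$mode,
               pools = lapply(model$tbv$pools, as.list),
               bounds = as.list(model$tbv$bounds)),
    meta = model$meta)
  # I(17) significant digits: doubles survive the round trip bit for bit
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

df_to_edges <- function(df)
  lapply(seq_len(nrow(df)),
         function(i) list(parent = df$parent[i], child = df$child[i]))

edges_to_df <- function(lst) {
  if (length(lst) == 0)
    return(data.frame(parent = character(0), child = character(0)))
  data.frame(parent = vapply(lst, `[[`, "", "parent"),
             child = vapply(lst, `[[`, "", "child"))
}

#' @rdname write_dbn
#' @export
read_dbn <- function(path) {
  x <- jsonlite::read_json(path)
  schema <- schema_from_list(x$schema)
  constraints <- edge_constraints(
    edges_to_df(x$constraints$mandatory),
    edges_to_df(x$constraints$forbidden),
    unlist(x$constraints$no_parent_vars) %||% character(0))
  st <- structure(list(
    static_edges = edges_to_df(x$structure$static_edges),
    inter_parents = lapply(x$structure$inter_parents,
                           function(p) unlist(p) %||% character(0))),
    class = "dbn_structure")
  cpts <- lapply(x$cpts, function(cpt) {
    prob <- do.call(rbind, lapply(cpt$prob, function(rw)
      as.numeric(unlist(rw))))
    parent_levels <- lapply(cpt$parent_levels, unlist)
    list(child = cpt$child,
         parents = unlist(cpt$parents) %||% character(0),
         child_levels = unlist(cpt$child_levels),
         parent_levels = parent_levels,
         parent_card = vapply(parent_levels, length, 0L),
         prob = prob, n_avail = cpt$n_avail, ess = cpt$ess)
  })
  names(cpts) <- vapply(cpts, `[[`, "", "child")
  tbv <- list(mode = x$tbv$mode,
              pools = lapply(x$tbv$pools, function(p)
                as.numeric(unlist(p)) %||% numeric(0)),
              bounds = as.numeric(unlist(x$tbv$bounds)))
  names(tbv$pools) <- names(x$tbv$pools)
  two_slice_dbn(schema, st, cpts, tbv, constraints,
                meta = x$meta %||% list())
}
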