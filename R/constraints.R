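# Edge constraints encoding domain knowledge for structure learning.

#' Edge constraint set
#'
#' Structure learning honours three kinds of constraint: layer rules
#' (derived from variable roles, see Details), explicit mandatory edges
#' (never removed) and explicit forbidden edges (never added).
#'
#' Layer rules: a static variable may depend only on other static
#' variables (contemporaneous); a dynamic, outcome or tbv variable at
#' slice t may depend on statics and on any slice-(t-1) variable except
#' survival (transitions always start from an alive state, so survival
#' carries no information as a parent); tso is never a child (it advances
#' deterministically as tso + tbv); variables in `no_parent_vars` accept no
#' parents at all (exogenous demographics such as sex).
#'
#' @param mandatory data.frame with columns `parent`, `child`; edges always
#'   present in learned structures.
#' @param forbidden data.frame with columns `parent`, `child`; edges never
#'   present.
#' @param no_parent_vars character vector of exogenous variables.
#' @return an object of class `edge_constraints`.
#' @export
edge_constraints <- function(mandatory = NULL, forbidden = NULL,
                             no_parent_vars = character(0)) {
  empty <- data.frame(parent = character(0), child = character(0))
  mandatory <- if (is.null(mandatory)) empty else mandatory
  forbidden <- if (is.null(forbidden)) empty else forbidden
  key <- function(df) paste(df$parent, df$child, sep = "->")
  if (length(intersect(key(mandatory), key(forbidden))) > 0)
    abort_als("an edge cannot be both mandatory and forbidden")
  structure(list(mandatory = mandatory, forbidden = forbidden,
                 no_parent_vars = no_parent_vars),
            class = "edge_constraints")
}

#' Default constraint set for a schema
#'
#' Mandates the dependence of each MiToS domain flag and of survival on
#' the time since onset (the progressive nature of the disease), and
#' declares sex, age at onset and medical centre exogenous (nothing may
#' point into them). All of it is editable: the returned object is plain
#' data.
#'
#' @param schema a `cohort_schema`.
#' @return an `edge_constraints` object.
#' @export
default_constraints <- function(schema) {
  children <- c(intersect(MITOS_VARS, names(schema$variables)), SURVIVAL_VAR)
  mandatory <- data.frame(parent = TSO_VAR, child = children)
  exo <- intersect(c("sex", "age_onset", "centre"), schema$static_names)
  edge_constraints(mandatory = mandatory, no_parent_vars = exo)
}

# is (parent -> child) admissible under roles + explicit constraints?
edge_allowed <- function(schema, constraints, parent, child) {
  if (parent == child && child %in% schema$static_names) return(FALSE)
  if (child %in% constraints$no_parent_vars) return(FALSE)
  if (child == TSO_VAR) return(FALSE)
  if (parent == SURVIVAL_VAR) return(FALSE)
  roles_ok <- if (child %in% schema$static_names) {
    parent %in% schema$static_names
  } else if (child %in% dbn_children(schema)) {
    parent %in% dbn_parents(schema)
  } else FALSE
  if (!roles_ok) return(FALSE)
  f <- constraints$forbidden
  !any(f$parent == parent & f$child == child)
}

validate_constraints <- function(schema, constraints) {
  m <- constraints$mandatory
  for (i in seq_len(nrow(m)))
    if (!edge_allowed(schema, constraints, m$parent[i], m$child[i]))
      abort_als("mandatory edge %s -> %s violates layer rules or forbidden set",
                m$parent[i], m$child[i])
  static_m <- m[m$child %in% schema$static_names, , drop = FALSE]
  if (nrow(static_m) > 0 && !is_acyclic(static_m, schema$static_names))
    abort_als("mandatory edges force a cycle in the static layer")
  invisible(TRUE)
}

mandatory_parents <- function(constraints, child) {
  m <- constraints$mandatory
  m$parent[m$child == child]
}

# acyclicity of a static-layer edge set (data.frame parent/child)
is_acyclic <- function(edges, nodes) {
  if (nrow(edges) == 0) return(TRUE)
  indeg <- setNames(rep(0L, length(nodes)), nodes)
  tb <- table(edges$child)
  indeg[names(tb)] <- as.integer(tb)
  active <- rep(TRUE, nrow(edges))
  queue <- nodes[indeg == 0]
  seen <- 0L
  while (length(queue) > 0) {
    n <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    out <- which(active & edges$parent == n)
    for (i in out) {
      active[i] <- FALSE
      ch <- edges$child[i]
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  seen == length(nodes)
}

#' Read / write constraints as YAML
#' @param constraints an `edge_constraints` object.
#' @param path file path.
#' @export
write_constraints <- function(constraints, path) {
  edges_list <- function(df)
    lapply(seq_len(nrow(df)),
           function(i) list(parent = df$parent[i], child = df$child[i]))
  yaml::write_yaml(list(mandatory = edges_list(constraints$mandatory),
                        forbidden = edges_list(constraints$forbidden),
                        no_parent_vars = as.list(constraints$no_parent_vars)),
                   path)
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  x <- yaml::read_yaml(path)
  edges_df <- function(lst) {
    if (length(lst) == 0)
      return(data.frame(parent = character(0), child = character(0)))
    data.frame(parent = vapply(lst, `[[`, "", "parent"),
               child = vapply(lst, `[[`, "", "child"))
  }
  edge_constraints(edges_df(x$mandatory), edges_df(x$forbidden),
                   unlist(x$no_parent_vars) %||% character(0))
}
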