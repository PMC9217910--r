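# Max-Min Hill-Climbing structure learning for the two-slice DBN.
#
# Phase 1 (MMPC) screens a candidate parent set per child with G2
# conditional-independence tests using the max-min association heuristic.
# Phase 2 hill-climbs over add/delete moves restricted to the candidates
# (plus mandatory edges), maximizing the total BIC. Inter-slice families
# decompose: every dynamic/outcome/tbv child is optimized independently
# because all of its parents live at slice t-1 (no intra-slice edges).
# The static layer is a joint greedy search with acyclicity checks.

#' MMHC learning parameters
#'
#' @param alpha significance level of the G2 conditional-independence
#'   tests in the candidate-screening phase (default 0.05).
#' @param max_sx maximum conditioning-set size in the screening phase
#'   (default 3).
#' @param max_parents maximum number of parents per child (default 4).
#' @return a named list.
#' @export
mmhc_params <- function(alpha = 0.05, max_sx = 3L, max_parents = 4L) {
  list(alpha = alpha, max_sx = max_sx, max_parents = max_parents)
}

# all subsets of `set` with size <= k (including the empty set)
subsets_upto <- function(set, k) {
  out <- list(character(0))
  for (m in seq_len(min(k, length(set)))) {
    cmb <- utils::combn(set, m, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# max p-value of (child _|_ x | S) over subsets S of cpc, |S| <= max_sx
max_assoc_p <- function(tdata, schema, child, x, cpc, params) {
  pmax_val <- 0
  for (S in subsets_upto(cpc, params$max_sx)) {
    p <- g2_pvalue(tdata, schema, child, x, S)
    if (p > pmax_val) pmax_val <- p
    if (pmax_val >= params$alpha) break # already screened out
  }
  pmax_val
}

# MMPC candidate parents for one child from a candidate pool
mmpc_child <- function(tdata, schema, child, pool, params,
                       seed_cpc = character(0)) {
  cpc <- seed_cpc
  pool <- sort(setdiff(pool, cpc))
  repeat {
    if (length(pool) == 0) break
    pvals <- vapply(pool, function(x)
      max_assoc_p(tdata, schema, child, x, cpc, params), 0)
    best <- which.min(pvals) # lexicographic tie-break: pool is sorted
    if (pvals[best] >= params$alpha) break
    cpc <- c(cpc, pool[best])
    pool <- pool[-best]
  }
  # backward pass: drop members that became independent
  for (x in setdiff(cpc, seed_cpc)) {
    rest <- setdiff(cpc, x)
    if (max_assoc_p(tdata, schema, child, x, rest, params) >= params$alpha)
      cpc <- rest
  }
  sort(cpc)
}

# greedy parent-set search for one child over a fixed candidate set;
# mandatory parents are never removed. Returns the parent set.
climb_family <- function(tdata, schema, child, candidates, mandatory,
                         params, bic_cache) {
  score_of <- function(parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    if (is.null(bic_cache[[key]]))
      bic_cache[[key]] <- family_bic(tdata, schema, child, sort(parents))
    bic_cache[[key]]
  }
  parents <- sort(mandatory)
  current <- score_of(parents)
  repeat {
    moves <- list()
    if (length(parents) < params$max_parents)
      for (p in sort(setdiff(candidates, parents)))
        moves[[length(moves) + 1L]] <- list(op = "add", p = p)
    for (p in sort(setdiff(parents, mandatory)))
      moves[[length(moves) + 1L]] <- list(op = "del", p = p)
    if (length(moves) == 0) break
    deltas <- vapply(moves, function(m) {
      np <- if (m$op == "add") c(parents, m$p) else setdiff(parents, m$p)
      score_of(np) - current
    }, 0)
    best <- which.max(deltas) # first of ties; moves are in sorted order
    if (deltas[best] <= 1e-9) break
    m <- moves[[best]]
    parents <- sort(if (m$op == "add") c(parents, m$p)
                    else setdiff(parents, m$p))
    current <- current + deltas[best]
  }
  parents
}

#' Learn the two-slice DBN structure by Max-Min Hill-Climbing
#'
#' @param tdata a `transition_dataset` from [build_transition_dataset()].
#' @param schema the `cohort_schema`.
#' @param constraints an [edge_constraints()] object.
#' @param params learning parameters, see [mmhc_params()].
#' @return an object of class `dbn_structure`: `static_edges` (data.frame
#'   parent/child over static variables) and `inter_parents` (named list:
#'   slice-t child -> character vector of slice-(t-1)/static parents).
#' @export
mmhc_learn <- function(tdata, schema, constraints = default_constraints(schema),
                       params = mmhc_params()) {
  validate_constraints(schema, constraints)
  bic_cache <- new.env(parent = emptyenv())

  # --- inter-slice families (independent per child) ---
  inter_parents <- list()
  for (child in dbn_children(schema)) {
    pool <- Filter(function(p) edge_allowed(schema, constraints, p, child),
                   dbn_parents(schema))
    mand <- mandatory_parents(constraints, child)
    cpc <- mmpc_child(tdata, schema, child, pool, params, seed_cpc = mand)
    inter_parents[[child]] <-
      climb_family(tdata, schema, child, union(cpc, mand), mand, params,
                   bic_cache)
  }

  # --- static layer (joint greedy search with acyclicity) ---
  statics <- schema$static_names
  cpc_static <- list()
  for (child in statics) {
    pool <- Filter(function(p) edge_allowed(schema, constraints, p, child),
                   setdiff(statics, child))
    mand <- intersect(mandatory_parents(constraints, child), statics)
    cpc_static[[child]] <-
      union(mmpc_child(tdata, schema, child, pool, params, seed_cpc = mand),
            mand)
  }
  m <- constraints$mandatory
  edges <- m[m$child %in% statics & m$parent %in% statics, , drop = FALSE]
  parents_of <- function(edges, child) edges$parent[edges$child == child]
  fam_scores <- setNames(vapply(statics, function(ch)
    family_bic(tdata, schema, ch, sort(parents_of(edges, ch))), 0), statics)
  repeat {
    best <- NULL
    for (child in statics) {
      cur_par <- parents_of(edges, child)
      mand <- intersect(mandatory_parents(constraints, child), statics)
      cand_add <- if (length(cur_par) < params$max_parents)
        sort(setdiff(cpc_static[[child]], cur_par)) else character(0)
      for (p in cand_add) {
        ne <- rbind(edges, data.frame(parent = p, child = child))
        if (!is_acyclic(ne, statics)) next
        delta <- family_bic(tdata, schema, child, sort(c(cur_par, p))) -
          fam_scores[[child]]
        if (delta > 1e-9 && (is.null(best) || delta > best$delta))
          best <- list(edges = ne, child = child, delta = delta,
                       parents = sort(c(cur_par, p)))
      }
      for (p in sort(setdiff(cur_par, mand))) {
        ne <- edges[!(edges$parent == p & edges$child == child), ,
                    drop = FALSE]
        delta <- family_bic(tdata, schema, child, sort(setdiff(cur_par, p))) -
          fam_scores[[child]]
        if (delta > 1e-9 && (is.null(best) || delta > best$delta))
          best <- list(edges = ne, child = child, delta = delta,
                       parents = sort(setdiff(cur_par, p)))
      }
    }
    if (is.null(best)) break
    edges <- best$edges
    fam_scores[[best$child]] <- fam_scores[[best$child]] + best$delta
  }
  rownames(edges) <- NULL

  st <- structure(list(static_edges = edges, inter_parents = inter_parents),
                  class = "dbn_structure")
  assert_structure(st, schema, constraints)
  st
}

# post-hoc constraint assertion, run after every structure search
assert_structure <- function(st, schema, constraints) {
  m <- constraints$mandatory
  for (i in seq_len(nrow(m))) {
    child <- m$child[i]; parent <- m$parent[i]
    present <- if (child %in% schema$static_names) {
      any(st$static_edges$parent == parent & st$static_edges$child == child)
    } else parent %in% st$inter_parents[[child]]
    if (!present)
      abort_als("constraint violation: mandatory edge %s -> %s absent",
                parent, child)
  }
  all_edges <- rbind(
    st$static_edges,
    do.call(rbind, c(list(data.frame(parent = character(0),
                                     child = character(0))),
                     lapply(names(st$inter_parents), function(ch)
                       if (length(st$inter_parents[[ch]]) == 0) NULL else
                         data.frame(parent = st$inter_parents[[ch]],
                                    child = ch)))))
  for (i in seq_len(nrow(all_edges)))
    if (!edge_allowed(schema, constraints, all_edges$parent[i],
                      all_edges$child[i]))
      abort_als("constraint violation: edge %s -> %s is not admissible",
                all_edges$parent[i], all_edges$child[i])
  if (!is_acyclic(st$static_edges, schema$static_names))
    abort_als("static layer is cyclic")
  invisible(TRUE)
}

#' @export
print.dbn_structure <- function(x, ...) {
  cat("two-slice DBN structure\n static edges:\n")
  if (nrow(x$static_edges) == 0) cat("  (none)\n") else
    for (i in seq_len(nrow(x$static_edges)))
      cat(sprintf("  %s -> %s\n", x$static_edges$parent[i],
                  x$static_edges$child[i]))
  cat(" inter-slice parents:\n")
  for (ch in names(x$inter_parents))
    cat(sprintf("  %s(t) <- {%s}\n", ch,
                paste(x$inter_parents[[ch]], collapse = ", ")))
  invisible(x)
}
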