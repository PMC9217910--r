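# MAP parameter estimation with Dirichlet smoothing.

# build one conditional probability table under a uniform Dirichlet prior
# of total mass `ess` spread over the whole table:
#   p = (count + ess/cells) / (rowtotal + ess*r/cells)
# so unseen parent configurations get a uniform row and every entry stays
# strictly positive whenever ess > 0.
fit_cpt <- function(tdata, schema, child, parents, ess = 1) {
  fv <- family_view(tdata, schema, child, parents)
  counts <- family_counts(fv)
  q <- nrow(counts); r <- ncol(counts)
  cells <- q * r
  a <- ess / cells
  prob <- (counts + a) / (rowSums(counts) + a * r)
  if (ess == 0) { # maximum-likelihood limit; unseen rows fall back to uniform
    zero <- rowSums(counts) == 0
    prob[zero, ] <- 1 / r
  }
  list(child = child, parents = parents, child_levels = fv$child_levels,
       parent_levels = fv$parent_levels, parent_card = fv$parent_card,
       prob = prob, n_avail = sum(counts), ess = ess)
}

#' MAP-fit the conditional probability tables of a structure
#'
#' Fits one conditional table per family (inter-slice children on the
#' transition rows, static variables on one baseline row per patient)
#' under a uniform Dirichlet prior of total mass `ess` per table, using
#' available cases. Also stores the empirical pools of continuous
#' time-between-visit values per tbv bin, used by the simulator to convert
#' a sampled tbv bin back to months.
#'
#' @param tdata a `transition_dataset`.
#' @param schema the `cohort_schema`.
#' @param structure a `dbn_structure` from [mmhc_learn()].
#' @param ess equivalent sample size (pseudo-count mass) per table,
#'   default 1.
#' @param constraints the constraint set the structure was learned under
#'   (stored in the model for reproducibility).
#' @param pool_cap maximum number of stored empirical tbv values per bin;
#'   larger pools are thinned to an evenly spaced quantile grid.
#' @return an object of class `two_slice_dbn`.
#' @export
map_fit <- function(tdata, schema, structure, ess = 1,
                    constraints = default_constraints(schema),
                    pool_cap = 1000L) {
  cpts <- list()
  for (child in names(structure$inter_parents))
    cpts[[child]] <- fit_cpt(tdata, schema, child,
                             structure$inter_parents[[child]], ess)
  for (child in schema$static_names) {
    par <- structure$static_edges$parent[structure$static_edges$child == child]
    cpts[[child]] <- fit_cpt(tdata, schema, child, sort(par), ess)
  }
  tbv_spec <- schema$variables[[TBV_VAR]]
  raw <- tdata$tbv_raw
  lev <- tdata$to$tbv
  pools <- lapply(tbv_spec$levels, function(lv) {
    x <- sort(raw[!is.na(lev) & lev == lv & !is.na(raw)])
    if (length(x) > pool_cap)
      x <- unname(quantile(x, seq(0, 1, length.out = pool_cap), type = 7))
    x
  })
  names(pools) <- tbv_spec$levels
  lo <- if (length(raw) > 0) max(0.1, min(raw, na.rm = TRUE)) else 0.5
  hi <- if (length(raw) > 0) max(raw, na.rm = TRUE) else
    2 * max(tbv_spec$cuts, 6)
  bounds <- c(min(lo, tbv_spec$cuts[1]), tbv_spec$cuts,
              max(hi, 2 * tbv_spec$cuts[length(tbv_spec$cuts)]))
  two_slice_dbn(schema, structure, cpts,
                tbv = list(mode = "bin-empirical", pools = pools,
                           bounds = bounds),
                constraints = constraints,
                meta = list(ess = ess, n_transitions = tdata$n,
                            n_patients = nrow(tdata$baseline)))
}

#' Learn a two-slice DBN from a discretized cohort
#'
#' Convenience wrapper: builds the transition dataset, learns the
#' structure by MMHC and MAP-fits the parameters.
#'
#' @inheritParams map_fit
#' @param cohort a discretized `als_cohort`.
#' @param params MMHC parameters, see [mmhc_params()].
#' @return a `two_slice_dbn`.
#' @export
learn_dbn <- function(cohort, schema,
                      constraints = default_constraints(schema),
                      params = mmhc_params(), ess = 1) {
  tdata <- build_transition_dataset(cohort, schema)
  st <- mmhc_learn(tdata, schema, constraints, params)
  map_fit(tdata, schema, st, ess = ess, constraints = constraints)
}
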