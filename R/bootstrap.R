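# Bootstrap edge-confidence analysis: a weighted partially directed
# acyclic graph (WPDAG) whose edge weights count, over bootstrap
# resamples of patients, how often each edge appears in the learned
# structure.

structure_edges <- function(st) {
  inter <- do.call(rbind, lapply(names(st$inter_parents), function(ch) {
    p <- st$inter_parents[[ch]]
    if (length(p) == 0) return(NULL)
    data.frame(parent = p, child = ch)
  }))
  rbind(st$static_edges, inter)
}

#' Bootstrap edge confidence (WPDAG)
#'
#' Resamples patients with replacement `n_boot` times, relearns the
#' structure on each resample, and returns per-edge occurrence counts.
#' Mandatory edges always weigh `n_boot`; forbidden edges never appear.
#' Samples on which learning fails are skipped and logged; the result
#' reports the effective number of samples.
#'
#' @param cohort a discretized `als_cohort`.
#' @param schema the `cohort_schema`.
#' @param n_boot number of bootstrap samples (default 100).
#' @param constraints an [edge_constraints()] object.
#' @param params MMHC parameters.
#' @param seed integer seed.
#' @return an object of class `wpdag`: `edges` (data.frame parent, child,
#'   weight), `n_boot`, `n_effective`.
#' @export
bootstrap_wpdag <- function(cohort, schema, n_boot = 100L,
                            constraints = default_constraints(schema),
                            params = mmhc_params(), seed = 1L) {
  stopifnot(n_boot >= 1)
  n_boot <- as.integer(n_boot)
  set.seed(derive_seed(seed, "wpdag"))
  ids <- cohort$outcomes$patient_id
  counts <- new.env(parent = emptyenv())
  n_eff <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    boot <- resample_cohort(cohort, take)
    st <- tryCatch({
      tdata <- build_transition_dataset(boot, schema)
      mmhc_learn(tdata, schema, constraints, params)
    }, error = function(e) {
      warn_als("bootstrap sample %d skipped: %s", b, conditionMessage(e))
      NULL
    })
    if (is.null(st)) next
    n_eff <- n_eff + 1L
    ed <- structure_edges(st)
    for (i in seq_len(nrow(ed))) {
      key <- paste(ed$parent[i], ed$child[i], sep = "->")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  edges <- if (length(keys) == 0)
    data.frame(parent = character(0), child = character(0),
               weight = integer(0))
  else {
    pc <- do.call(rbind, strsplit(keys, "->", fixed = TRUE))
    data.frame(parent = pc[, 1], child = pc[, 2],
               weight = vapply(keys, function(k) counts[[k]], 0L),
               row.names = NULL)
  }
  edges <- edges[order(-edges$weight, edges$parent, edges$child), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, n_boot = n_boot, n_effective = n_eff),
            class = "wpdag")
}

# duplicate-aware patient resampling: the j-th draw of a patient gets a
# fresh id so visits stay grouped per drawn patient
resample_cohort <- function(cohort, take) {
  new_ids <- make.unique(take, sep = "__")
  vl <- split(seq_len(nrow(cohort$visits)), cohort$visits$patient_id)
  vrows <- lapply(seq_along(take), function(j) {
    rows <- cohort$visits[vl[[take[j]]], , drop = FALSE]
    rows$patient_id <- new_ids[j]
    rows
  })
  visits <- do.call(rbind, vrows)
  rownames(visits) <- NULL
  om <- cohort$outcomes[match(take, cohort$outcomes$patient_id), ,
                        drop = FALSE]
  om$patient_id <- new_ids
  rownames(om) <- NULL
  als_cohort(visits, om)
}

#' @export
print.wpdag <- function(x, ...) {
  cat(sprintf("WPDAG from %d/%d bootstrap samples\n", x$n_effective,
              x$n_boot))
  print(head(x$edges, 20))
  invisible(x)
}
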