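# BIC family scoring and G2 conditional-independence tests under the
# available-cases treatment of missing data: each child-parent family is
# scored only on rows where the child and all its parents are observed,
# so no imputation is ever needed.

# counts matrix (n_config x r) over available cases
family_counts <- function(fv) {
  ok <- !is.na(fv$y)
  if (!is.null(fv$X)) ok <- ok & stats::complete.cases(fv$X)
  y <- fv$y[ok]
  n_config <- prod(c(fv$parent_card, 1))
  if (length(fv$parent_card) == 0) {
    cfg <- rep(1L, length(y))
  } else {
    cfg <- config_index(fv$X[ok, , drop = FALSE], fv$parent_card)
  }
  code <- cfg + n_config * (y - 1L)
  counts <- tabulate(code, nbins = n_config * fv$r)
  matrix(counts, nrow = n_config, ncol = fv$r)
}

#' BIC score of one child-parent family
#'
#' Score = maximized multinomial log-likelihood of the child given its
#' parents minus the penalty `0.5 * ln(N) * q * (r - 1)` where `N` is the
#' number of available cases (rows with child and all parents observed),
#' `q` the number of parent configurations and `r` the number of child
#' levels. Higher is better. Zero available rows scores `-Inf` with a
#' warning.
#'
#' @param tdata a `transition_dataset`.
#' @param schema the `cohort_schema`.
#' @param child child variable name.
#' @param parents character vector of parent names (may be empty).
#' @return scalar BIC score.
#' @export
family_bic <- function(tdata, schema, child, parents = character(0)) {
  fv <- family_view(tdata, schema, child, parents)
  counts <- family_counts(fv)
  N <- sum(counts)
  if (N == 0) {
    warn_als("family_bic: no available cases for child '%s'", child)
    return(-Inf)
  }
  rowtot <- rowSums(counts)
  nz <- counts > 0
  ll <- sum(counts[nz] * log(counts[nz] / rowtot[row(counts)[nz]]))
  q <- prod(c(fv$parent_card, 1))
  ll - 0.5 * log(N) * q * (fv$r - 1)
}

# G2 test of child _|_ x given conditioning set S (all names), on available
# cases. Returns the p-value; df uses declared level cardinalities.
g2_pvalue <- function(tdata, schema, child, x, S = character(0)) {
  fv <- family_view(tdata, schema, child, c(x, S))
  ok <- !is.na(fv$y) & stats::complete.cases(fv$X)
  y <- fv$y[ok]
  if (length(y) == 0) return(1)
  X <- fv$X[ok, , drop = FALSE]
  cx <- fv$parent_card[1]
  r <- fv$r
  cs <- prod(c(fv$parent_card[-1], 1))
  s_cfg <- if (length(S) == 0) rep(1L, length(y)) else
    config_index(X[, -1, drop = FALSE], fv$parent_card[-1])
  code <- X[, 1] + cx * (y - 1L) + cx * r * (s_cfg - 1L)
  n_xys <- array(tabulate(code, nbins = cx * r * cs), dim = c(cx, r, cs))
  n_xs <- apply(n_xys, c(1, 3), sum)
  n_ys <- apply(n_xys, c(2, 3), sum)
  n_s <- apply(n_xys, 3, sum)
  g2 <- 0
  for (k in seq_len(cs)) {
    if (n_s[k] == 0) next
    e <- outer(n_xs[, k], n_ys[, k]) / n_s[k]
    o <- n_xys[, , k]
    pos <- o > 0 & e > 0
    g2 <- g2 + 2 * sum(o[pos] * log(o[pos] / e[pos]))
  }
  df <- (cx - 1) * (r - 1) * cs
  if (df <= 0) return(1)
  stats::pchisq(g2, df, lower.tail = FALSE)
}
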