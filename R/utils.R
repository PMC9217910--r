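#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rbinom runif rlnorm pchisq chisq.test
#'   kruskal.test setNames sd complete.cases
#' @importFrom utils head read.csv write.csv combn
#' @importFrom graphics par plot lines legend polygon hist
#' @importFrom grDevices adjustcolor
NULL

# Deterministic 31-bit seed derived from a master seed and a string id.
# Plain polynomial string hash; all arithmetic kept below 2^53 so it is
# exact in doubles, result always in [1, 2^31 - 2].
derive_seed <- function(master, id) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- (as.numeric(master) %% m)
  codes <- utf8ToInt(as.character(id))
  for (cc in codes) h <- (h * 131 + cc) %% m
  h <- (h * 48271) %% m
  as.integer(h + 1)
}

# value %in% (lo, hi] interval index for cuts; cuts empty -> all 1
cut_index <- function(x, cuts) {
  if (length(cuts) == 0L) return(rep(1L, length(x)))
  idx <- findInterval(x, cuts, left.open = FALSE) + 1L
  # findInterval is left-closed; we need right-closed intervals, i.e. a
  # value exactly equal to a cut belongs to the lower bin.
  for (i in seq_along(cuts)) idx[!is.na(x) & x == cuts[i]] <- i
  idx[is.na(x)] <- NA_integer_
  idx
}

# mixed-radix configuration index: vals is an integer matrix (rows = cases,
# cols = parents), card the per-column cardinalities. Returns 1-based codes,
# NA if any entry NA.
config_index <- function(vals, card) {
  if (length(card) == 0L) return(rep(1L, nrow(vals)))
  idx <- rep(1, nrow(vals))
  stride <- 1
  for (j in seq_along(card)) {
    idx <- idx + (vals[, j] - 1) * stride
    stride <- stride * card[j]
  }
  as.integer(idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_als <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

warn_als <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)
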