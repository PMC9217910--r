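# ALSFRS-R -> MiToS staging.

#' Convert ALSFRS-R item scores to MiToS domain impairment flags
#'
#' The revised ALS Functional Rating Scale scores 12 items from 0 (worst)
#' to 4 (normal). The Milano-Torino staging system declares loss of
#' independence in four functional domains (walking/self-care, swallowing,
#' communication, breathing) when specific items drop to or below a cut
#' score; the per-domain items, cuts and combination rule come from the
#' threshold table (see [default_mitos_thresholds()]).
#'
#' A missing required item makes the corresponding domain flag `NA`
#' (propagated, never imputed), unless the observed items already decide
#' the flag: under an OR rule one lost observed item suffices for 1, under
#' an AND rule one intact observed item suffices for 0.
#'
#' @param scores a data.frame (or single named vector) with columns
#'   `alsfrs_1` .. `alsfrs_12`, integer scores 0..4.
#' @param thresholds threshold table; default [default_mitos_thresholds()].
#' @return data.frame with one `"0"`/`"1"` character column per domain
#'   flag (`mitos_walking`, `mitos_swallowing`, `mitos_communication`,
#'   `mitos_breathing`).
#' @export
alsfrs_to_mitos <- function(scores, thresholds = default_mitos_thresholds()) {
  if (!is.data.frame(scores)) scores <- as.data.frame(as.list(scores))
  for (it in unique(unlist(lapply(thresholds, `[[`, "items")))) {
    if (!it %in% names(scores))
      abort_als("alsfrs_to_mitos: missing item column '%s'", it)
    s <- scores[[it]]
    if (any(!is.na(s) & (s < 0 | s > 4)))
      abort_als("alsfrs_to_mitos: item '%s' outside 0..4", it)
  }
  out <- data.frame(row.names = seq_len(nrow(scores)))
  for (dom in names(thresholds)) {
    rule <- thresholds[[dom]]
    lost <- mapply(function(item, cut) scores[[item]] <= cut,
                   rule$items, rule$cuts)
    lost <- matrix(lost, nrow = nrow(scores))
    flag <- if (rule$rule == "OR") {
      # lost if any item lost; NA only if undecided
      apply(lost, 1, function(z)
        if (any(z %in% TRUE)) 1L else if (anyNA(z)) NA_integer_ else 0L)
    } else {
      apply(lost, 1, function(z)
        if (any(z %in% FALSE)) 0L else if (anyNA(z)) NA_integer_ else 1L)
    }
    out[[dom]] <- ifelse(is.na(flag), NA_character_, as.character(flag))
  }
  out
}
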