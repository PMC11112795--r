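#' Relative methylation decrease after demethylating treatment
#'
#' The decrease at a CpG unit is expressed relative to its pre-treatment
#' level: `(before - after) / before * 100` percent. Negative values
#' (an increase) keep their sign. Reports round to 1 decimal, half away
#' from zero.
#'
#' @param before,after methylation levels in \[0,1\]; `before` must be
#'   positive (vectorized).
#' @param digits decimals to round to (default 1, the report convention);
#'   `NULL` returns the raw value.
#' @return percent decrease.
#' @export
relative_decrease <- function(before, after, digits = 1) {
  if (any(before < 0 | before > 1) || any(after < 0 | after > 1))
    ms_stop("levels must lie in [0,1]")
  if (any(before == 0))
    ms_stop("relative decrease undefined at before = 0")
  x <- (before - after) / before * 100
  if (is.null(digits)) x else round_half_away(x, digits)
}

#' Read a demethylation panel TSV
#'
#' Columns: `unit_id`, `level_untreated`, `level_treated`, and optional
#' `level_reference` (untreated normal-cell control).
#'
#' @param path TSV path (with header).
#' @return panel `data.frame`.
#' @export
read_demeth_panel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("unit_id", "level_untreated", "level_treated") %in% names(df)))
    ms_stop("panel needs unit_id, level_untreated, level_treated columns")
  if (!"level_reference" %in% names(df)) df$level_reference <- NA_real_
  lev <- c(df$level_untreated, df$level_treated,
           df$level_reference[!is.na(df$level_reference)])
  if (any(lev < 0 | lev > 1)) ms_stop("panel levels must lie in [0,1]")
  if (anyDuplicated(df$unit_id)) ms_stop("duplicate unit ids")
  df
}

#' Demethylation response of a CpG-unit panel
#'
#' Computes the absolute and relative methylation decrease of every
#' selected unit and identifies the unit with the largest relative
#' decrease (lexicographic unit-id tie-break). Units with an untreated
#' level of 0 have no defined relative decrease; they are excluded with a
#' message.
#'
#' @param panel panel `data.frame` ([simulate_demeth_panel()] or
#'   [read_demeth_panel()]).
#' @param loci_subset optional character vector of unit ids to restrict
#'   to (must all be present in the panel).
#' @return list with `records` (`unit_id`, `abs_delta`, `rel_decrease`
#'   in percent, 1 decimal) and `top` (the argmax record, or `NULL` for
#'   an empty selection).
#' @export
panel_response <- function(panel, loci_subset = NULL) {
  if (!is.null(loci_subset)) {
    missing <- setdiff(loci_subset, panel$unit_id)
    if (length(missing) > 0)
      ms_stop("unknown unit id(s): ", paste(missing, collapse = ", "))
    panel <- panel[panel$unit_id %in% loci_subset, , drop = FALSE]
  }
  if (nrow(panel) == 0)
    return(list(records = data.frame(unit_id = character(),
                                     abs_delta = numeric(),
                                     rel_decrease = numeric()),
                top = NULL))
  zero <- panel$level_untreated == 0
  if (any(zero)) {
    message("unit(s) with untreated level 0 excluded: ",
            paste(panel$unit_id[zero], collapse = ", "))
    panel <- panel[!zero, , drop = FALSE]
  }
  if (nrow(panel) == 0)
    return(list(records = data.frame(unit_id = character(),
                                     abs_delta = numeric(),
                                     rel_decrease = numeric()),
                top = NULL))
  rec <- data.frame(
    unit_id = panel$unit_id,
    abs_delta = panel$level_untreated - panel$level_treated,
    rel_decrease = relative_decrease(panel$level_untreated,
                                     panel$level_treated),
    row.names = NULL)
  ord <- order(-rec$rel_decrease, rec$unit_id)
  list(records = rec, top = rec[ord[1], , drop = FALSE])
}
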