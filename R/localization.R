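#' Cytoplasmic/nuclear relative concentration index (RCI)
#'
#' `log2((cytoplasmic + pseudocount) / (nuclear + pseudocount))`. Positive
#' values mark cytoplasmic enrichment, negative values nuclear enrichment.
#' The pseudocount keeps the index defined at zero expression. Exactly
#' antisymmetric under swapping the two inputs.
#'
#' @param cytoplasmic_expr,nuclear_expr non-negative expression values
#'   (vectorized).
#' @param pseudocount positive stabilizer, default 0.01.
#' @return numeric RCI value(s), log2 units.
#' @export
compute_rci <- function(cytoplasmic_expr, nuclear_expr, pseudocount = 0.01) {
  if (any(cytoplasmic_expr < 0) || any(nuclear_expr < 0)) {
    stop("expression values must be >= 0", call. = FALSE)
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  log2((cytoplasmic_expr + pseudocount) / (nuclear_expr + pseudocount))
}

#' Assign compartments from an RCI value
#'
#' `rci < -neutral_band` assigns the nucleus, `rci > +neutral_band` the
#' cytoplasm, and `|rci| <= neutral_band` both (dual residency), reflecting
#' that transcripts near parity are observed in both compartments. Monotone in
#' `rci`: increasing the index never removes the cytoplasm once assigned.
#'
#' @param rci RCI value (log2 units).
#' @param neutral_band half-width of the dual-residency band, >= 0
#'   (default 0.5).
#' @return character vector of compartments.
#' @export
assign_compartment <- function(rci, neutral_band = 0.5) {
  stopifnot(neutral_band >= 0)
  if (rci < -neutral_band) "nucleus"
  else if (rci > neutral_band) "cytoplasm"
  else c("nucleus", "cytoplasm")
}

#' Build compartment profiles from a cytoplasmic/nuclear expression table
#'
#' @param cn_table data.frame with columns `symbol`, `cytoplasmic`, `nuclear`
#'   (schema `cn_expression`).
#' @param neutral_band see [assign_compartment()].
#' @param pseudocount see [compute_rci()].
#' @return data.frame `symbol`, `rci`, `compartments` (semicolon-joined),
#'   `source = "computed"` — directly consumable by
#'   [colocalization_filter()].
#' @export
compartment_profiles <- function(cn_table, neutral_band = 0.5, pseudocount = 0.01) {
  rci <- compute_rci(cn_table$cytoplasmic, cn_table$nuclear, pseudocount)
  comp <- vapply(rci, function(x) {
    paste(assign_compartment(x, neutral_band), collapse = ";")
  }, character(1))
  data.frame(symbol = cn_table$symbol, rci = rci, compartments = comp,
             source = "computed", stringsAsFactors = FALSE)
}
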