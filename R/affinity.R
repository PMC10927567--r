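# iBAQ-based relative affinity estimation.
#
# TREX releases the fraction of each protein bound to the digested RNA
# region. Relating the released amount (iBAQ in the +RNase H eluate minus
# the -RNase H background) to the protein's total cellular amount (iBAQ in
# a matched total-proteome run) gives a relative affinity:
# Ka = [RNA bound] / [Total] = iBAQ_TREX / iBAQ_total.

#' Estimate relative RNA affinities from iBAQ values
#'
#' `ibaq_trex` is the mean iBAQ over +RNase H samples minus the mean over
#' -RNase H samples; `ka = ibaq_trex / ibaq_total` with `ibaq_total` the
#' mean over quantified total-proteome runs. Missing iBAQ values in the
#' -RNase H control are treated as 0 (absence of background release); a
#' protein missing in every +RNase H replicate, missing in every total run,
#' or with non-positive released amount gets an undefined `ka` and is
#' excluded from ranking (released material cannot be negative).
#'
#' @param quant A [trex_quant] object with an iBAQ table and samples in
#'   groups `plus_rnaseh`, `minus_rnaseh` and `total`.
#' @param significant Optional character vector of significant protein ids
#'   (e.g. from [permutation_fdr()]); recorded in the `significant` column,
#'   all proteins are still computed.
#' @return Tibble with `protein_id`, `ibaq_trex`, `ibaq_total`, `ka`,
#'   `rank` (dense, 1 = highest ka, `NA` when ka undefined) and
#'   `significant`, sorted by rank.
#' @export
estimate_affinity <- function(quant, significant = NULL) {
  stopifnot(inherits(quant, "trex_quant"))
  if (is.null(quant$ibaq)) {
    abort("`quant` has no iBAQ table; affinity estimation needs iBAQ values.")
  }
  m <- quant_matrix(quant$ibaq)
  idx <- group_columns(m, quant$samples)
  for (g in c("plus_rnaseh", "minus_rnaseh", "total")) {
    if (is.null(idx[[g]]) || length(idx[[g]]) == 0L) {
      abort(sprintf("No samples in group `%s`.", g))
    }
  }
  zero_mean <- function(j) {
    x <- m[, j, drop = FALSE]
    x[is.na(x)] <- 0
    rowMeans(x)
  }
  plus <- m[, idx$plus_rnaseh, drop = FALSE]
  all_missing_plus <- rowSums(!is.na(plus)) == 0L
  ibaq_plus <- zero_mean(idx$plus_rnaseh)
  ibaq_minus <- zero_mean(idx$minus_rnaseh)
  # total proteome: average over quantified runs; undefined if none
  ibaq_total <- rowMeans(m[, idx$total, drop = FALSE], na.rm = TRUE)
  ibaq_total[is.nan(ibaq_total)] <- NA_real_
  ibaq_trex <- ibaq_plus - ibaq_minus
  ka <- ifelse(
    !all_missing_plus & ibaq_trex > 0 &
      !is.na(ibaq_total) & ibaq_total > 0,
    ibaq_trex / ibaq_total,
    NA_real_
  )
  out <- tibble::tibble(
    protein_id = rownames(m),
    ibaq_trex = unname(ibaq_trex),
    ibaq_total = unname(ibaq_total),
    ka = unname(ka),
    rank = dplyr::dense_rank(dplyr::desc(ka)),
    significant = if (is.null(significant)) {
      NA
    } else {
      rownames(m) %in% significant
    }
  )
  dplyr::arrange(out, .data$rank)  # NAs (undefined ka) sort last
}
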