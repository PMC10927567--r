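# Depletion-efficiency and specificity QC: 2^-dCT qPCR summaries and the
# quantile-based transcriptome outlier test for RNase H specificity.

#' Relative expression from qPCR Ct values (2^-dCT)
#'
#' `2^-(ct_target - mean(ct_housekeepers))`: one PCR cycle difference halves
#' the estimate. Housekeeping Cts are aggregated by their arithmetic mean
#' (equivalently, the geometric mean of their expression levels).
#'
#' @param ct_target Ct of the target assay (numeric vector allowed).
#' @param ct_housekeepers Numeric vector of housekeeping Cts for the same
#'   sample (e.g. GAPDH and RPS18).
#' @return Relative expression level(s).
#' @examples
#' relative_expression(21, c(20, 20))  # dCT = 1 -> 0.5
#' @export
relative_expression <- function(ct_target, ct_housekeepers) {
  if (length(ct_housekeepers) == 0L) {
    abort("At least one housekeeping Ct is required.")
  }
  if (anyNA(ct_target) || anyNA(ct_housekeepers)) {
    abort("All Ct values must be present.")
  }
  if (any(c(ct_target, ct_housekeepers) <= 0)) {
    abort("Ct values must be positive.")
  }
  2^-(ct_target - mean(ct_housekeepers))
}

#' Summarise a qPCR Ct table into relative expression levels
#'
#' @param ct_tbl Data frame with columns `sample_id`, `target`, `ct` and
#'   logical `housekeeping`; every sample needs at least one housekeeping
#'   row.
#' @return Tibble of non-housekeeping rows with a `relative_expression`
#'   column (2^-dCT against the sample's mean housekeeping Ct).
#' @export
qpcr_relative_expression <- function(ct_tbl) {
  need <- c("sample_id", "target", "ct", "housekeeping")
  if (!is.data.frame(ct_tbl) || !all(need %in% names(ct_tbl))) {
    abort("`ct_tbl` needs columns sample_id, target, ct, housekeeping.")
  }
  hk <- ct_tbl |>
    dplyr::filter(.data$housekeeping) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(hk_ct = mean(.data$ct), .groups = "drop")
  no_hk <- setdiff(unique(ct_tbl$sample_id), hk$sample_id)
  if (length(no_hk) > 0L) {
    abort(sprintf(
      "Sample(s) without a housekeeping target: %s",
      paste(no_hk, collapse = ", ")
    ))
  }
  ct_tbl |>
    dplyr::filter(!.data$housekeeping) |>
    dplyr::inner_join(hk, by = "sample_id") |>
    dplyr::mutate(relative_expression = 2^-(.data$ct - .data$hk_ct)) |>
    dplyr::select(-"hk_ct") |>
    tibble::as_tibble()
}

#' Depletion efficiency
#'
#' Fraction of the target removed: `1 - level_treated / level_control`.
#' 1 means complete depletion, 0 none; negative values indicate apparent
#' enrichment.
#'
#' @param level_treated,level_control Relative expression in the RNase
#'   H-treated and control samples (`level_control > 0`).
#' @return Depletion fraction.
#' @export
depletion_efficiency <- function(level_treated, level_control) {
  if (any(level_control <= 0)) {
    abort("`level_control` must be positive.")
  }
  1 - level_treated / level_control
}

#' Transcriptome-wide depletion specificity test
#'
#' Tests whether the RNase H digestion removed anything beyond the intended
#' target. Per transcript the score is the displacement from the identity
#' line of the control-vs-treated group-mean scatter
#' (`mean_control - mean_treated`, in log2 TPM units). A robust null spread
#' is estimated from the stated quantile of the absolute deviations from
#' the median score, `sigma = quantile(|score - median|, q) / qnorm((1+q)/2)`,
#' and each transcript gets a two-sided Normal tail p value, BH-corrected;
#' an outlier is a transcript with `q_value <= alpha`.
#'
#' The table is processed with the same Perseus-style steps as the
#' proteomics data: log2 transform, minimum-valid filter (>= `min_valid` in
#' at least one group) and Gaussian downshift imputation.
#'
#' @param tpm Wide tibble of TPM values (`transcript_id` + sample columns;
#'   zeros are converted to missing before the log transform).
#' @param samples Sample sheet with groups `rnaseh` and `control`, at least
#'   3 replicates each.
#' @param quantile_cut Quantile defining the robust null spread (default
#'   0.95).
#' @param alpha BH FDR level for the outlier call (default 0.05).
#' @param min_valid,downshift,width,seed Passed to the filtering and
#'   imputation steps.
#' @return Tibble with `transcript_id`, `mean_control`, `mean_treated`
#'   (log2 TPM), `score`, `p`, `q_value` and `outlier`, sorted by
#'   decreasing score.
#' @export
transcriptome_specificity <- function(tpm, samples, quantile_cut = 0.95,
                                      alpha = 0.05, min_valid = 3,
                                      downshift = 1.8, width = 0.3,
                                      seed = NULL) {
  check_scalar_number(quantile_cut, "quantile_cut", min = 0, max = 1,
                      strict_min = TRUE)
  if (quantile_cut >= 1) abort("`quantile_cut` must be in (0, 1).")
  samples <- check_samples(samples, groups = c("rnaseh", "control"))
  sizes <- table(samples$group)
  if (length(sizes) < 2L || any(sizes < 3L)) {
    abort("The outlier test needs >= 3 replicates in each group.")
  }
  id_col <- "transcript_id"
  tpm <- tpm |>
    dplyr::mutate(dplyr::across(
      -dplyr::all_of(id_col), ~ ifelse(!is.na(.x) & .x == 0, NA_real_, .x)
    ))
  processed <- tpm |>
    log2_transform(id_col = id_col) |>
    filter_min_valid(samples, min_valid = min_valid, id_col = id_col) |>
    impute_gaussian_downshift(
      downshift = downshift, width = width, seed = seed, id_col = id_col
    )
  m <- quant_matrix(processed, id_col)
  idx <- group_columns(m, samples)
  mean_control <- rowMeans(m[, idx$control, drop = FALSE])
  mean_treated <- rowMeans(m[, idx$rnaseh, drop = FALSE])
  score <- mean_control - mean_treated
  med <- median(score)
  sigma <- quantile(abs(score - med), quantile_cut, names = FALSE) /
    qnorm((1 + quantile_cut) / 2)
  if (sigma <= 0) {
    abort("Degenerate score distribution: robust spread is zero.")
  }
  p <- 2 * pnorm(-abs(score - med) / sigma)
  q <- benjamini_hochberg(p)
  tibble::tibble(
    transcript_id = rownames(m),
    mean_control = mean_control,
    mean_treated = mean_treated,
    score = score,
    p = p,
    q_value = q,
    outlier = q <= alpha
  ) |>
    dplyr::arrange(dplyr::desc(.data$score))
}
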