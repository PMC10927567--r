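# Internal helpers shared across modules.

# Wide quantification tables are tibbles whose first column is `protein_id`
# (or another id column) and whose remaining columns are one numeric column
# per sample; NA encodes a missing (unquantified) value, never 0.

# Extract the numeric matrix (proteins x samples) from a wide table.
quant_matrix <- function(tbl, id_col = "protein_id") {
  if (!is.data.frame(tbl)) {
    abort("`tbl` must be a data frame with an id column and sample columns.")
  }
  if (!id_col %in% names(tbl)) {
    abort(sprintf("Column `%s` not found in table.", id_col))
  }
  value_cols <- setdiff(names(tbl), id_col)
  if (length(value_cols) == 0L) {
    abort("Table has no sample columns.")
  }
  m <- as.matrix(tbl[value_cols])
  if (!is.numeric(m)) {
    abort("Sample columns must all be numeric.")
  }
  rownames(m) <- as.character(tbl[[id_col]])
  m
}

# Rebuild a wide tibble from a matrix, preserving the id column.
matrix_to_tbl <- function(m, id_col = "protein_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1)
  out
}

# Validate a sample sheet and return it with columns sample_id, group,
# replicate. `groups` optionally restricts the admissible group labels.
check_samples <- function(samples, groups = NULL) {
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "group") %in% names(samples))) {
    abort("`samples` must be a data frame with columns sample_id and group.")
  }
  samples <- tibble::as_tibble(samples)
  if (anyDuplicated(samples$sample_id)) {
    abort("Duplicate sample_id in sample sheet.")
  }
  if (!is.null(groups) && !all(samples$group %in% groups)) {
    bad <- setdiff(unique(samples$group), groups)
    abort(sprintf("Unknown group label(s): %s", paste(bad, collapse = ", ")))
  }
  if (!"replicate" %in% names(samples)) {
    samples <- samples |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(replicate = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  dup <- samples |>
    dplyr::count(.data$group, .data$replicate) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort("Replicate ids must be unique within each group.")
  }
  samples
}

# Columns of `m` belonging to each group, as a named list of column indices.
group_columns <- function(m, samples) {
  missing_cols <- setdiff(samples$sample_id, colnames(m))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "Sample(s) in sheet but not in table: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  split(match(samples$sample_id, colnames(m)), samples$group)
}

# Run `expr` under a fixed RNG seed without touching the caller's RNG state;
# with seed = NULL the current RNG stream is used (non-reproducible).
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(seed, expr)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    abort(sprintf("`%s` = %g is out of range.", name, x))
  }
  invisible(x)
}
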