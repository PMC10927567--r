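# MaxQuant proteinGroups parsing, the trex_quant container, and iBAQ.

#' Construct a TREX quantification object
#'
#' Bundles a wide label-free intensity table, an optional iBAQ table of the
#' same shape, and a sample sheet. Wide tables have a `protein_id` column
#' plus one numeric column per sample; `NA` encodes a missing quantification
#' and is distinct from 0 (zeros are rejected as undefined on the log scale
#' downstream).
#'
#' @param intensity Wide tibble of intensities (`protein_id` + sample
#'   columns).
#' @param samples Sample sheet: data frame with `sample_id`, `group`
#'   (`plus_rnaseh`, `minus_rnaseh` or `total`) and optional `replicate`.
#' @param ibaq Optional wide tibble of iBAQ values, same rows/columns as
#'   `intensity`.
#' @param proteins Optional per-protein annotation tibble (must contain
#'   `protein_id`).
#' @return A list of class `trex_quant` with elements `intensity`, `ibaq`,
#'   `samples`, `proteins`.
#' @export
trex_quant <- function(intensity, samples, ibaq = NULL, proteins = NULL) {
  samples <- check_samples(
    samples, groups = c("plus_rnaseh", "minus_rnaseh", "total")
  )
  m <- quant_matrix(intensity)
  if (any(m < 0, na.rm = TRUE)) {
    abort("Intensities must be non-negative.")
  }
  missing_cols <- setdiff(samples$sample_id, colnames(m))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "Sample sheet names samples absent from the table: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!is.null(ibaq)) {
    mi <- quant_matrix(ibaq)
    if (!identical(dim(mi), dim(m)) ||
        !identical(rownames(mi), rownames(m))) {
      abort("`ibaq` must have the same proteins and samples as `intensity`.")
    }
    if (any(mi < 0, na.rm = TRUE)) abort("iBAQ values must be non-negative.")
    ibaq <- tibble::as_tibble(ibaq)
  }
  if (is.null(proteins)) {
    proteins <- tibble::tibble(protein_id = intensity$protein_id)
  }
  structure(
    list(
      intensity = tibble::as_tibble(intensity),
      ibaq = ibaq,
      samples = samples,
      proteins = tibble::as_tibble(proteins)
    ),
    class = "trex_quant"
  )
}

#' @export
print.trex_quant <- function(x, ...) {
  cat(sprintf(
    "<trex_quant> %d proteins x %d samples (%s)%s\n",
    nrow(x$intensity), nrow(x$samples),
    paste(sprintf(
      "%s: %d", names(table(x$samples$group)), table(x$samples$group)
    ), collapse = ", "),
    if (is.null(x$ibaq)) "" else ", with iBAQ"
  ))
  invisible(x)
}

#' @describeIn trex_quant Long-format view: one row per protein x sample,
#'   with `intensity`, `ibaq` (if present), `group` and `replicate`.
#' @param x A `trex_quant` object.
#' @param ... Unused.
#' @method tidy trex_quant
#' @export
tidy.trex_quant <- function(x, ...) {
  long <- x$intensity |>
    tidyr::pivot_longer(-"protein_id",
      names_to = "sample_id", values_to = "intensity"
    )
  if (!is.null(x$ibaq)) {
    long_i <- x$ibaq |>
      tidyr::pivot_longer(-"protein_id",
        names_to = "sample_id", values_to = "ibaq"
      )
    long <- dplyr::left_join(long, long_i,
      by = c("protein_id", "sample_id")
    )
  }
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Parse a MaxQuant-style proteinGroups table
#'
#' Reads the tab-delimited proteinGroups dialect: per-sample quantification
#' columns prefixed `"LFQ intensity "` (or `"iBAQ "`), and the quality flag
#' columns `Reverse`, `Potential contaminant` and `Only identified by site`
#' marked with `"+"`. Flagged rows are removed by default (standard Perseus
#' practice) and zeros are recorded as missing values, since a zero LFQ
#' intensity means "not quantified", not "absent at level 0".
#'
#' @param path Path to a tab-delimited proteinGroups file.
#' @param samples Sample sheet (`sample_id`, `group`, optional `replicate`);
#'   `sample_id` must match the suffix of the quantification columns.
#' @param intensity_prefix Column prefix for the main quantification values
#'   (default `"LFQ intensity "`; use `"Intensity "` for raw intensities).
#' @param ibaq_prefix Column prefix for iBAQ values (default `"iBAQ "`);
#'   iBAQ columns are optional in the file.
#' @param remove_flagged Drop reverse-database, contaminant and
#'   identified-by-site rows (default `TRUE`).
#' @param id_col,gene_col Names of the protein id and gene name columns.
#' @return A [trex_quant] object.
#' @export
read_protein_groups <- function(path, samples,
                                intensity_prefix = "LFQ intensity ",
                                ibaq_prefix = "iBAQ ",
                                remove_flagged = TRUE,
                                id_col = "Protein IDs",
                                gene_col = "Gene names") {
  samples <- check_samples(
    samples, groups = c("plus_rnaseh", "minus_rnaseh", "total")
  )
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!id_col %in% names(raw)) {
    abort(sprintf("Protein id column `%s` not found.", id_col))
  }
  int_cols <- paste0(intensity_prefix, samples$sample_id)
  if (!any(int_cols %in% names(raw))) {
    abort(sprintf(
      "No quantification columns with prefix `%s` match the sample sheet.",
      intensity_prefix
    ))
  }
  missing_int <- setdiff(int_cols, names(raw))
  if (length(missing_int) > 0L) {
    abort(sprintf(
      "Missing quantification column(s): %s",
      paste(missing_int, collapse = ", ")
    ))
  }
  if (remove_flagged) {
    for (flag in c("Reverse", "Potential contaminant",
                   "Only identified by site")) {
      if (flag %in% names(raw)) {
        raw <- raw[is.na(raw[[flag]]) | raw[[flag]] != "+", ]
      }
    }
  }
  ids <- raw[[id_col]]
  if (anyDuplicated(ids)) {
    warn("Duplicate protein ids; keeping the first occurrence of each.")
    raw <- raw[!duplicated(ids), ]
    ids <- raw[[id_col]]
  }
  parse_block <- function(cols) {
    m <- vapply(cols, function(cl) {
      v <- suppressWarnings(as.numeric(raw[[cl]]))
      v[!is.na(v) & v == 0] <- NA_real_  # zero means unquantified
      v
    }, numeric(nrow(raw)))
    m <- matrix(m, nrow = nrow(raw),
                dimnames = list(NULL, samples$sample_id))
    dplyr::bind_cols(
      tibble::tibble(protein_id = ids),
      tibble::as_tibble(m)
    )
  }
  intensity <- parse_block(int_cols)
  ibaq_cols <- paste0(ibaq_prefix, samples$sample_id)
  ibaq <- if (all(ibaq_cols %in% names(raw))) parse_block(ibaq_cols) else NULL
  proteins <- tibble::tibble(
    protein_id = ids,
    gene_name = if (gene_col %in% names(raw)) raw[[gene_col]] else NA_character_
  )
  trex_quant(intensity, samples, ibaq = ibaq, proteins = proteins)
}

#' Write / re-read a trex_quant object as plain TSV + CSV
#'
#' `write_quant_tables()` writes `<stem>_intensity.tsv`, `<stem>_ibaq.tsv`
#' (if present) and `<stem>_samples.csv`; `read_quant_tables()` reloads them.
#' Values round-trip exactly (shortest round-trip double representation).
#'
#' @param quant A `trex_quant` object.
#' @param stem Output path stem.
#' @return The (re-read) `trex_quant` object, invisibly for the writer.
#' @export
write_quant_tables <- function(quant, stem) {
  stopifnot(inherits(quant, "trex_quant"))
  # serialize doubles with 17 significant digits so values survive the
  # text round trip bit-exactly
  full_precision <- function(tbl) {
    dplyr::mutate(tbl, dplyr::across(
      dplyr::where(is.double),
      ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))
    ))
  }
  readr::write_tsv(full_precision(quant$intensity),
                   paste0(stem, "_intensity.tsv"))
  if (!is.null(quant$ibaq)) {
    readr::write_tsv(full_precision(quant$ibaq), paste0(stem, "_ibaq.tsv"))
  }
  readr::write_csv(quant$samples, paste0(stem, "_samples.csv"))
  invisible(quant)
}

#' @rdname write_quant_tables
#' @export
read_quant_tables <- function(stem) {
  # values are parsed with strtod (via as.numeric) for a correctly rounded,
  # bit-exact round trip of the 17-digit serialization
  read_wide <- function(path) {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE) |>
      dplyr::mutate(dplyr::across(-"protein_id", as.numeric))
  }
  intensity <- read_wide(paste0(stem, "_intensity.tsv"))
  ibaq_path <- paste0(stem, "_ibaq.tsv")
  ibaq <- if (file.exists(ibaq_path)) read_wide(ibaq_path)
  samples <- readr::read_csv(
    paste0(stem, "_samples.csv"),
    col_types = readr::cols(
      sample_id = "c", group = "c", replicate = "i"
    ), progress = FALSE
  )
  trex_quant(intensity, samples, ibaq = ibaq)
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Count theoretically observable tryptic peptides
#'
#' Digests a protein sequence in silico with trypsin specificity — cleave
#' after K or R except when the next residue is P, no missed cleavages — and
#' counts the peptides whose length falls within the observable window used
#' by iBAQ (6 to 30 amino acids by convention).
#'
#' @param protein_seq Character vector of protein sequences (standard 20
#'   amino-acid alphabet).
#' @param min_len,max_len Observable peptide length bounds in residues.
#' @return Integer vector of peptide counts.
#' @examples
#' count_tryptic_peptides("AAAAAKAAAAAAR")
#' @export
count_tryptic_peptides <- function(protein_seq, min_len = 6, max_len = 30) {
  check_scalar_number(min_len, "min_len", min = 1)
  check_scalar_number(max_len, "max_len", min = min_len)
  vapply(protein_seq, function(s) {
    if (is.na(s) || nchar(s) == 0L) return(0L)
    s <- toupper(s)
    bad <- setdiff(unique(strsplit(s, "")[[1]]), AA_ALPHABET)
    if (length(bad) > 0L) {
      abort(sprintf(
        "Invalid amino-acid character(s): %s", paste(bad, collapse = ", ")
      ))
    }
    peptides <- strsplit(s, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
    sum(nchar(peptides) >= min_len & nchar(peptides) <= max_len)
  }, integer(1), USE.NAMES = FALSE)
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' iBAQ divides a protein's summed peptide intensity by its number of
#' theoretically observable tryptic peptides, giving a within-sample proxy
#' for protein copy number.
#'
#' @param total_intensity Numeric vector of summed intensities (>= 0, `NA`
#'   for missing).
#' @param peptide_count Integer vector of observable peptide counts (from
#'   [count_tryptic_peptides()]), recycled against `total_intensity`.
#' @return Numeric vector: `total_intensity / peptide_count`, `NA` where the
#'   intensity is missing or the peptide count is zero.
#' @export
compute_ibaq <- function(total_intensity, peptide_count) {
  if (any(total_intensity < 0, na.rm = TRUE)) {
    abort("Intensities must be non-negative.")
  }
  if (any(peptide_count < 0, na.rm = TRUE)) {
    abort("Peptide counts must be non-negative.")
  }
  out <- total_intensity / peptide_count
  out[!is.na(peptide_count) & peptide_count == 0L] <- NA_real_
  out
}
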