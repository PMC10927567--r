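# Tiling antisense probe design and off-target screening.
#
# TREX confers region specificity through unmodified DNA oligonucleotides
# annealed along the RNA region of interest; RNase H then degrades the RNA
# within each RNA:DNA hybrid. Probes are designed non-overlapping, tiling the
# region completely, around 60 nt long and never shorter than 30 nt (RNase H
# needs a stable hybrid) nor longer than 90 nt.

PROBE_ALPHABET <- c("A", "C", "G", "T", "U", "N")

check_nucleotide <- function(seq, name = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single character string.", name))
  }
  s <- toupper(seq)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), PROBE_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Invalid nucleotide character(s) in %s: %s",
      name, paste(bad, collapse = ", ")
    ))
  }
  s
}

#' Antisense (reverse-complement) sequence
#'
#' Returns the reverse complement of a nucleotide sequence as DNA, reading U
#' as T. This is the orientation of a DNA oligonucleotide fully complementary
#' to the given RNA, i.e. the probe sequence for an RNA target window.
#'
#' @param seq Character vector of nucleotide sequences (alphabet A, C, G,
#'   T/U, N; case-insensitive).
#' @return Character vector of DNA reverse complements, upper case with U
#'   canonicalized to T. Applying `antisense()` twice returns the input with
#'   T canonicalization.
#' @examples
#' antisense("AUGC")
#' antisense(antisense("ACGTTG"))
#' @export
antisense <- function(seq) {
  if (length(seq) == 0L) return(character())
  vapply(seq, function(s) {
    s <- check_nucleotide(s)
    s <- chartr("U", "T", s)
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

gc_fraction <- function(seq) {
  stringr::str_count(seq, "[GCgc]") / nchar(seq)
}

#' Design non-overlapping tiling antisense probes
#'
#' Tiles a target RNA region completely (no gaps, no overlaps) with antisense
#' DNA oligonucleotides. The probe count is `round(L / target_len)`
#' (half-up), clamped so that every probe length lies in
#' `[min_len, max_len]`; the region length is then split as evenly as
#' possible across probes (lengths differ by at most 1 nt, longer probes
#' first). Each probe sequence is the DNA reverse complement of its target
#' window, so a 164-nt target yields 3 probes and a ~13.4-kb target yields
#' 223 probes with the defaults.
#'
#' @param sequence Target region sequence (RNA or DNA alphabet, single
#'   string).
#' @param target_id Identifier of the target region.
#' @param target_len Desired average probe length in nt (default 60).
#' @param min_len,max_len Hard bounds on probe length in nt (defaults 30 and
#'   90).
#' @param offset 0-based start of the region on its parent transcript; only
#'   shifts reported coordinates.
#' @return A tibble of class `trex_probes` with one row per probe: columns
#'   `probe_id`, `target_id`, `target_start`, `target_end` (0-based,
#'   half-open, on the region's parent coordinates), `length`, `gc`
#'   (fraction), `sequence` (antisense DNA). Attribute `coverage_fraction`
#'   is the tiled fraction of the region (1 for the default gap-free
#'   design).
#' @examples
#' probes <- design_tiling_probes(strrep("ACGU", 41), target_id = "U1")
#' nrow(probes)
#' @export
design_tiling_probes <- function(sequence, target_id = "target",
                                 target_len = 60, min_len = 30, max_len = 90,
                                 offset = 0) {
  s <- check_nucleotide(sequence, "sequence")
  check_scalar_number(target_len, "target_len", min = 1)
  check_scalar_number(min_len, "min_len", min = 1)
  check_scalar_number(max_len, "max_len", min = min_len)
  if (target_len < min_len || target_len > max_len) {
    abort("`target_len` must lie within [min_len, max_len].")
  }
  len <- nchar(s)
  if (len < min_len) {
    abort(sprintf(
      "Target region is %d nt, shorter than the minimum probe length (%d nt).",
      len, min_len
    ))
  }
  n <- floor(len / target_len + 0.5)     # round half-up
  n <- max(n, ceiling(len / max_len))    # keep every probe <= max_len
  n <- min(n, floor(len / min_len))      # keep every probe >= min_len
  base <- len %/% n
  rem <- len %% n
  lengths <- c(rep(base + 1L, rem), rep(base, n - rem))
  ends <- cumsum(lengths)
  starts <- ends - lengths
  windows <- stringr::str_sub(s, starts + 1L, ends)
  probe_seq <- antisense(windows)
  out <- tibble::tibble(
    probe_id = sprintf("%s_probe_%03d", target_id, seq_len(n)),
    target_id = target_id,
    target_start = as.integer(starts + offset),
    target_end = as.integer(ends + offset),
    length = as.integer(lengths),
    gc = gc_fraction(probe_seq),
    sequence = probe_seq
  )
  structure(
    out,
    class = c("trex_probes", class(out)),
    target_id = target_id,
    target_length = len,
    coverage_fraction = sum(lengths) / len
  )
}

# Largest m such that some length-m substring of `s` occurs in `transcript`.
# Seeded: containment is first tested at `seed_k`; the exact maximum is then
# located by bisection on the monotone containment predicate (if an m-mer of
# s occurs, so does some (m-1)-mer), so matches shorter than the seed are
# still reported exactly.
longest_match_in <- function(s, transcript, seed_k) {
  has_match <- function(m) {
    n_sub <- nchar(s) - m + 1L
    mers <- unique(stringr::str_sub(s, seq_len(n_sub), seq_len(n_sub) + m - 1L))
    any(stringr::str_detect(transcript, stringr::fixed(mers)))
  }
  if (has_match(seed_k)) {
    lo <- seed_k
    hi <- nchar(s)
  } else {
    lo <- 0L
    hi <- seed_k - 1L
  }
  while (lo < hi) {
    mid <- lo + (hi - lo + 1L) %/% 2L
    if (has_match(mid)) lo <- mid else hi <- mid - 1L
  }
  as.integer(lo)
}

#' Screen probes for off-target transcript matches
#'
#' For each probe x transcript pair, finds the longest exact match between
#' the probe's sense window (the targeted strand, i.e. the reverse complement
#' of the probe oligo) and the transcript, by seeded k-mer containment with
#' exact refinement. A probe is flagged when its longest match to a
#' transcript other than its declared target reaches `flag_len` — a proxy for
#' a strong BLAST hit against a reference transcriptome.
#'
#' @param probes A `trex_probes` tibble (or any data frame with `probe_id`,
#'   `target_id`, `sequence` columns; sequences in antisense orientation).
#' @param transcripts Named character vector of transcript sequences
#'   (DNA/RNA alphabet); names are transcript ids.
#' @param flag_len Minimum off-target exact-match length (nt) that flags a
#'   probe (default 18).
#' @param seed_k Seed k-mer length used for the containment search (default
#'   12; must not exceed `flag_len` nor the shortest probe).
#' @return Tibble with columns `probe_id`, `transcript_id`,
#'   `longest_exact_match` (nt) and `flagged`, sorted by decreasing match
#'   length.
#' @export
screen_off_targets <- function(probes, transcripts, flag_len = 18,
                               seed_k = 12) {
  if (!is.data.frame(probes) ||
      !all(c("probe_id", "target_id", "sequence") %in% names(probes))) {
    abort("`probes` must have columns probe_id, target_id and sequence.")
  }
  empty <- tibble::tibble(
    probe_id = character(), transcript_id = character(),
    longest_exact_match = integer(), flagged = logical()
  )
  if (nrow(probes) == 0L) return(empty)
  if (length(transcripts) == 0L) abort("`transcripts` must be non-empty.")
  if (is.null(names(transcripts)) || any(names(transcripts) == "")) {
    abort("`transcripts` must be a named character vector.")
  }
  check_scalar_number(seed_k, "seed_k", min = 1)
  if (seed_k > min(nchar(probes$sequence))) {
    abort("`seed_k` exceeds the shortest probe length.")
  }
  if (flag_len < seed_k) {
    abort("`flag_len` must be at least `seed_k`.")
  }
  sense <- antisense(probes$sequence)  # back to target-strand orientation
  tx <- vapply(names(transcripts), function(id) {
    chartr("U", "T", check_nucleotide(transcripts[[id]], id))
  }, character(1))
  grid <- tidyr::expand_grid(
    probe_idx = seq_len(nrow(probes)),
    transcript_id = names(tx)
  )
  grid |>
    dplyr::mutate(
      probe_id = probes$probe_id[.data$probe_idx],
      target_id = probes$target_id[.data$probe_idx],
      longest_exact_match = purrr::map2_int(
        .data$probe_idx, .data$transcript_id,
        function(i, t) longest_match_in(sense[[i]], tx[[t]], as.integer(seed_k))
      ),
      flagged = .data$longest_exact_match >= flag_len &
        .data$transcript_id != .data$target_id
    ) |>
    dplyr::arrange(dplyr::desc(.data$longest_exact_match)) |>
    dplyr::select("probe_id", "transcript_id", "longest_exact_match", "flagged")
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a named
#' character vector (upper case), suitable for [design_tiling_probes()] and
#' [screen_off_targets()]. FASTA headers are truncated at the first
#' whitespace.
#'
#' @param path Path to a FASTA file (DNA or RNA alphabet).
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Package Biostrings is required to read FASTA files.")
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write a probe set as TSV and optionally BED
#'
#' The TSV carries probe_id, target_id, start, end, length, GC fraction and
#' the antisense sequence; the BED6 file places each probe on the target's
#' parent coordinates on the minus strand (antisense orientation).
#'
#' @param probes A `trex_probes` tibble.
#' @param tsv Output TSV path.
#' @param bed Optional output BED path.
#' @return `probes`, invisibly.
#' @export
write_probes <- function(probes, tsv, bed = NULL) {
  readr::write_tsv(tibble::as_tibble(probes), tsv)
  if (!is.null(bed)) {
    bed_tbl <- tibble::tibble(
      chrom = probes$target_id,
      start = probes$target_start,
      end = probes$target_end,
      name = probes$probe_id,
      score = round(1000 * probes$gc),
      strand = "-"
    )
    readr::write_tsv(bed_tbl, bed, col_names = FALSE)
  }
  invisible(probes)
}

#' @export
print.trex_probes <- function(x, ...) {
  cat(sprintf(
    "<trex_probes> %d probes tiling %s (%d nt, %.1f%% covered)\n",
    nrow(x), attr(x, "target_id"), attr(x, "target_length"),
    100 * attr(x, "coverage_fraction")
  ))
  NextMethod()
}
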