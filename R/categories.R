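# Category over-representation analysis: two-sided Fisher's exact test on
# 2x2 tables with BH correction across annotation sets.

#' Read annotation sets from a GMT file
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   then member ids).
#' @return Named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("Package fgsea is required to read GMT files.")
  }
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L || any(lengths(sets) == 0L)) {
    abort("GMT file contains empty annotation sets.")
  }
  sets
}

# Two-sided Fisher exact p for a 2x2 table, by direct hypergeometric tail
# summation: sum the probabilities of all tables (same margins) whose point
# probability does not exceed the observed one (with the conventional
# 1 + 1e-7 relative tolerance, matching stats::fisher.test). Vectorised over
# tables.
fisher_p_two_sided <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b   # hits
  c1 <- a + c   # set members
  purrr::pmap_dbl(list(a, r1, c1, n), function(a_, r_, c_, n_) {
    lo <- max(0L, r_ + c_ - n_)
    hi <- min(r_, c_)
    dens <- dhyper(lo:hi, c_, n_ - c_, r_)
    obs <- dens[a_ - lo + 1L]
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  })
}

#' Fisher's exact over-representation test across annotation sets
#'
#' For each annotation set, builds the 2x2 table of hit/non-hit vs
#' member/non-member over the quantified universe, computes the two-sided
#' Fisher exact p value (hypergeometric tail summation), BH-corrects across
#' sets, and calls a set enriched when `q <= alpha` and the odds ratio
#' exceeds 1. Set members outside the universe are dropped (and counted).
#'
#' @param hits Character vector of hit protein ids (must be a subset of
#'   `universe`).
#' @param sets Named list of annotation sets (e.g. from [read_gmt()]).
#' @param universe Character vector of all quantified protein ids.
#' @param alpha BH FDR level for the enrichment call (default 0.02).
#' @return Tibble with `set_name`, counts `a` (hit & member), `b` (hit
#'   only), `c` (member only), `d` (neither), `n_dropped` (members outside
#'   the universe), `odds_ratio`, `p`, `q_value`, `enriched`, sorted by p.
#' @export
fisher_enrichment <- function(hits, sets, universe, alpha = 0.02) {
  hits <- unique(hits)
  universe <- unique(universe)
  if (length(hits) == 0L || length(universe) == 0L) {
    abort("`hits` and `universe` must be non-empty.")
  }
  if (!all(hits %in% universe)) {
    abort("All hits must belong to the universe of quantified proteins.")
  }
  if (length(sets) == 0L || is.null(names(sets))) {
    abort("`sets` must be a non-empty named list.")
  }
  rows <- purrr::imap(sets, function(members, nm) {
    members_all <- unique(members)
    members <- intersect(members_all, universe)
    a <- length(intersect(hits, members))
    b <- length(hits) - a
    c_ <- length(members) - a
    d <- length(universe) - a - b - c_
    tibble::tibble(
      set_name = nm, a = a, b = b, c = c_, d = d,
      n_dropped = length(members_all) - length(members)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$odds_ratio <- (out$a * out$d) / (out$b * out$c)
  out$p <- fisher_p_two_sided(out$a, out$b, out$c, out$d)
  out$q_value <- benjamini_hochberg(out$p)
  out$enriched <- out$q_value <= alpha &
    !is.na(out$odds_ratio) & out$odds_ratio > 1
  dplyr::arrange(out, .data$p)
}
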