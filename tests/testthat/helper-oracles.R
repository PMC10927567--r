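# Independent brute-force oracles and small fixture builders. These are
# deliberately written with plain loops and closed forms, separate from the
# package's vectorised implementations.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wide tibble from a matrix of values (NA = missing).
make_wide <- function(m, ids = sprintf("P%03d", seq_len(nrow(m))),
                      id_col = "protein_id") {
  colnames(m) <- colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  out <- tibble::as_tibble(m)
  out[[id_col]] <- ids
  out[, c(id_col, setdiff(names(out), id_col))]
}

# Two-group sample sheet (group A first).
make_samples <- function(n_a, n_b, group_a = "plus_rnaseh",
                         group_b = "minus_rnaseh",
                         ids = c(paste0("a", seq_len(n_a)),
                                 paste0("b", seq_len(n_b)))) {
  tibble::tibble(
    sample_id = ids,
    group = c(rep(group_a, n_a), rep(group_b, n_b)),
    replicate = c(seq_len(n_a), seq_len(n_b))
  )
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Longest common substring length by dynamic programming.
oracle_lcs <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- integer(length(B))
  best <- 0L
  for (i in seq_along(A)) {
    cur <- ifelse(B == A[i], c(0L, prev[-length(prev)]) + 1L, 0L)
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

# Character-by-character tryptic digestion (no regex): cleave after K/R
# unless followed by P; count peptides with length in [min_len, max_len].
oracle_tryptic_count <- function(seq, min_len = 6, max_len = 30) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n == 0) return(0L)
  lens <- integer(0)
  cur <- 0L
  for (i in seq_len(n)) {
    cur <- cur + 1L
    cut_here <- chars[i] %in% c("K", "R") &&
      (i == n || chars[i + 1] != "P")
    if (cut_here) {
      lens <- c(lens, cur)
      cur <- 0L
    }
  }
  if (cur > 0L) lens <- c(lens, cur)
  sum(lens >= min_len & lens <= max_len)
}

# Classical pooled two-sample t statistic (textbook formula).
oracle_pooled_t <- function(xa, xb) {
  na <- length(xa)
  nb <- length(xb)
  sp2 <- ((na - 1) * var(xa) + (nb - 1) * var(xb)) / (na + nb - 2)
  (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Exhaustive-permutation FDR, all in explicit loops. Returns q per row of m.
oracle_perm_fdr <- function(m, idx_a, idx_b, s0) {
  na <- length(idx_a)
  stat <- function(cols_a) {
    cols_b <- setdiff(c(idx_a, idx_b), cols_a)
    apply(m, 1, function(x) {
      xa <- x[cols_a]
      xb <- x[cols_b]
      sp2 <- ((na - 1) * var(xa) + (length(xb) - 1) * var(xb)) /
        (na + length(xb) - 2)
      (mean(xa) - mean(xb)) /
        (sqrt(sp2 * (1 / na + 1 / length(xb))) + s0)
    })
  }
  obs <- abs(stat(idx_a))
  splits <- combn(c(idx_a, idx_b), na, simplify = FALSE)
  perm <- vapply(splits, function(s) abs(stat(s)), numeric(nrow(m)))
  # FDR at each observed threshold, straight from the definition
  fdr_at <- vapply(obs, function(c_) {
    mean(apply(perm, 2, function(p) sum(p >= c_))) / sum(obs >= c_)
  }, numeric(1))
  q <- numeric(length(obs))
  for (i in seq_along(obs)) {
    q[i] <- min(fdr_at[obs <= obs[i]], 1)
  }
  q
}

# Two-sided Fisher exact p by direct tail summation using binomial
# coefficients (independent of dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r <- a + b
  k <- a + c
  support <- max(0, r + k - n):min(r, k)
  prob <- vapply(support, function(x) {
    exp(lchoose(k, x) + lchoose(n - k, r - x) - lchoose(n, r))
  }, numeric(1))
  obs <- prob[support == a]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}
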