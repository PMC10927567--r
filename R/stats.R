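# Perseus-style differential-release statistics: log transform, minimum-valid
# filtering, Gaussian downshift imputation, the S0-moderated two-sample test,
# permutation-based FDR, and the volcano significance boundary.

#' Log2-transform a wide quantification table
#'
#' Missing values stay missing; present values must be strictly positive
#' (zeros are required to be encoded as missing upstream, see
#' [read_protein_groups()]).
#'
#' @param tbl Wide tibble (`protein_id` + numeric sample columns).
#' @param id_col Name of the id column.
#' @return The table with all sample columns log2-transformed.
#' @export
log2_transform <- function(tbl, id_col = "protein_id") {
  m <- quant_matrix(tbl, id_col)
  if (any(m <= 0, na.rm = TRUE)) {
    abort("All present values must be > 0 before log2 transform; encode zeros as missing.")
  }
  tbl |> dplyr::mutate(
    dplyr::across(-dplyr::all_of(id_col), log2)
  )
}

#' Filter rows on minimum valid values per group
#'
#' Keeps proteins quantified in at least `min_valid` replicates in at least
#' one sample group — the standard label-free filter before imputation.
#'
#' @param tbl Wide tibble (`protein_id` + sample columns).
#' @param samples Sample sheet restricted to the groups under comparison.
#' @param min_valid Minimum number of present values required in some group
#'   (default 3 biological replicates).
#' @param id_col Name of the id column.
#' @return The filtered table (rows failing the rule dropped).
#' @export
filter_min_valid <- function(tbl, samples, min_valid = 3,
                             id_col = "protein_id") {
  samples <- check_samples(samples)
  m <- quant_matrix(tbl, id_col)
  idx <- group_columns(m, samples)
  if (min_valid > max(lengths(idx))) {
    abort(sprintf(
      "`min_valid` = %d exceeds the largest group size (%d).",
      min_valid, max(lengths(idx))
    ))
  }
  valid_per_group <- vapply(
    idx, function(j) rowSums(!is.na(m[, j, drop = FALSE])), numeric(nrow(m))
  )
  keep <- apply(cbind(valid_per_group), 1, max) >= min_valid
  tbl[keep, , drop = FALSE]
}

#' Gaussian downshift imputation of missing values
#'
#' Label-free missingness is concentrated at low abundance (left-censored,
#' missing-not-at-random), so missing cells are drawn from a Gaussian
#' shifted below each sample's observed log2-intensity distribution: for a
#' column with observed mean `m` and standard deviation `s`, imputed values
#' are drawn from Normal(m - downshift * s, (width * s)^2). Defaults are the
#' Perseus convention of a 1.8 s.d. downshift with 0.3 s.d. spread.
#'
#' @param tbl Wide tibble of log2 intensities.
#' @param downshift Downshift in column-s.d. units (default 1.8).
#' @param width Imputation spread in column-s.d. units (default 0.3).
#' @param seed Integer seed; the same seed reproduces the same table.
#' @param id_col Name of the id column.
#' @return The table with every missing cell imputed; present cells are
#'   untouched.
#' @export
impute_gaussian_downshift <- function(tbl, downshift = 1.8, width = 0.3,
                                      seed = NULL, id_col = "protein_id") {
  check_scalar_number(downshift, "downshift", min = 0)
  check_scalar_number(width, "width", min = 0, strict_min = TRUE)
  m <- quant_matrix(tbl, id_col)
  n_present <- colSums(!is.na(m))
  if (any(n_present < 2L)) {
    abort(sprintf(
      "Column(s) with fewer than 2 present values cannot be imputed: %s",
      paste(colnames(m)[n_present < 2L], collapse = ", ")
    ))
  }
  m_imp <- with_seed_or_not(seed, {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (!any(miss)) next
      mu <- mean(m[, j], na.rm = TRUE)
      s <- sd(m[, j], na.rm = TRUE)
      m[miss, j] <- rnorm(sum(miss), mean = mu - downshift * s,
                          sd = width * s)
    }
    m
  })
  out <- tbl
  out[setdiff(names(tbl), id_col)] <- tibble::as_tibble(m_imp)
  out
}

# Vectorised S0-moderated two-sample statistic over the rows of a matrix.
# Returns difference (A - B), d_stat and the two-sided t-approximation p.
s0_stat_matrix <- function(m, idx_a, idx_b, s0) {
  na <- length(idx_a)
  nb <- length(idx_b)
  xa <- m[, idx_a, drop = FALSE]
  xb <- m[, idx_b, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  df <- na + nb - 2L
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  difference <- ma - mb
  d <- difference / (se + s0)
  list(
    difference = difference,
    d_stat = d,
    p = 2 * pt(-abs(d), df = df),
    df = df
  )
}

#' S0-moderated two-sample test
#'
#' The SAM-style statistic used on TREX volcano plots: the pooled-variance
#' two-sample t statistic with an artificial within-groups standard
#' deviation `s0` added to the denominator, damping the significance of
#' proteins with small absolute log2 differences. With `s0 = 0` it reduces
#' exactly to the classical Student t statistic. The p value is the
#' two-sided tail of the t distribution with `nA + nB - 2` degrees of
#' freedom evaluated at the moderated statistic — an approximation;
#' significance calls should rest on the permutation FDR
#' ([permutation_fdr()]).
#'
#' @param x_a,x_b Numeric vectors of log2 intensities for the two groups
#'   (each of length >= 2, no missing values).
#' @param s0 Artificial within-groups standard deviation (default 0.1).
#' @return A one-row tibble with `difference` (mean A - mean B), `d_stat`,
#'   `p` and `df`.
#' @export
two_sample_s0_test <- function(x_a, x_b, s0 = 0.1) {
  check_scalar_number(s0, "s0", min = 0)
  if (length(x_a) < 2L || length(x_b) < 2L) {
    abort("Each group needs at least 2 values (pooled variance needs df >= 1).")
  }
  if (anyNA(x_a) || anyNA(x_b)) {
    abort("Missing values must be imputed before testing.")
  }
  st <- s0_stat_matrix(
    rbind(c(x_a, x_b)), seq_along(x_a), length(x_a) + seq_along(x_b), s0
  )
  tibble::tibble(
    difference = st$difference, d_stat = st$d_stat, p = st$p, df = st$df
  )
}

# All two-group label splits as a list of group-A column index vectors.
# Exhaustive when choose(n, nA) <= n_perm (identity split included);
# otherwise n_perm uniform random splits excluding the identity.
permutation_splits <- function(idx_a, idx_b, n_perm, seed) {
  cols <- c(idx_a, idx_b)
  na <- length(idx_a)
  n_all <- choose(length(cols), na)
  if (n_all <= n_perm) {
    splits <- combn(cols, na, simplify = FALSE)
    list(splits = splits, exhaustive = TRUE)
  } else {
    id <- sort(idx_a)
    splits <- with_seed_or_not(seed, {
      out <- vector("list", n_perm)
      i <- 1L
      while (i <= n_perm) {
        s <- sort(sample(cols, na))
        if (identical(s, id)) next
        out[[i]] <- s
        i <- i + 1L
      }
      out
    })
    list(splits = splits, exhaustive = FALSE)
  }
}

#' Permutation-based FDR for the S0-moderated test
#'
#' Computes the observed moderated statistic per protein, recomputes it
#' under sample-label permutations (exhaustively when the number of distinct
#' splits does not exceed `n_perm`, else `n_perm` uniform random splits
#' excluding the identity), and estimates for every threshold `c` in the
#' sorted observed `|d|`:
#' `FDR(c) = mean_perm #\{|d_perm| >= c\} / #\{|d_obs| >= c\}`.
#' A protein's q value is the smallest FDR over all thresholds that would
#' still call it (thresholds `<= |d|`), capped at 1, so q is non-increasing
#' in `|d|`. A protein is significant when `q <= alpha`.
#'
#' @param tbl Imputation-complete wide tibble of log2 intensities.
#' @param samples Sample sheet; only rows with `group` in
#'   `c(group_a, group_b)` are used.
#' @param group_a,group_b Group labels compared (difference = A - B).
#' @param s0 Artificial within-groups standard deviation (default 0.1).
#' @param alpha Permutation FDR significance level (default 0.05).
#' @param n_perm Number of permutations (default 250).
#' @param seed Integer seed for random splits.
#' @param id_col Name of the id column.
#' @return An object of class `trex_enrichment`: use [tidy()] for the
#'   per-protein table (`protein_id`, `difference`, `d_stat`, `p`, `q`,
#'   `significant`), [glance()] for a one-row summary, [autoplot()] for the
#'   volcano plot.
#' @export
permutation_fdr <- function(tbl, samples, group_a = "plus_rnaseh",
                            group_b = "minus_rnaseh", s0 = 0.1,
                            alpha = 0.05, n_perm = 250, seed = NULL,
                            id_col = "protein_id") {
  check_scalar_number(s0, "s0", min = 0)
  check_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  if (alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (n_perm < 1L) abort("`n_perm` must be at least 1.")
  samples <- check_samples(samples)
  samples <- samples[samples$group %in% c(group_a, group_b), ]
  m <- quant_matrix(tbl, id_col)
  if (anyNA(m)) {
    abort("Table contains missing values; impute before permutation testing.")
  }
  idx <- group_columns(m, samples)
  if (!all(c(group_a, group_b) %in% names(idx))) {
    abort("Both comparison groups must be present in the sample sheet.")
  }
  idx_a <- idx[[group_a]]
  idx_b <- idx[[group_b]]
  if (length(idx_a) < 2L || length(idx_b) < 2L) {
    abort("Each group needs at least 2 replicates.")
  }
  obs <- s0_stat_matrix(m, idx_a, idx_b, s0)
  perms <- permutation_splits(idx_a, idx_b, n_perm, seed)
  cols <- c(idx_a, idx_b)
  abs_perm <- unlist(lapply(perms$splits, function(a) {
    abs(s0_stat_matrix(m, a, setdiff(cols, a), s0)$d_stat)
  }))
  n_used <- length(perms$splits)

  abs_obs <- abs(obs$d_stat)
  ord <- order(abs_obs)                      # thresholds ascending
  thr <- abs_obs[ord]
  n <- length(thr)
  sorted_perm <- sort(abs_perm)
  # #{|d_perm| >= thr_k} averaged over permutations / #{|d_obs| >= thr_k}
  n_perm_ge <- length(sorted_perm) -
    findInterval(thr, sorted_perm, left.open = TRUE)
  n_obs_ge <- n - findInterval(thr, thr, left.open = TRUE)
  fdr_at_thr <- (n_perm_ge / n_used) / n_obs_ge
  q <- numeric(n)
  q[ord] <- pmin(cummin(fdr_at_thr), 1)
  result <- tibble::tibble(
    protein_id = rownames(m),
    difference = obs$difference,
    d_stat = obs$d_stat,
    p = obs$p,
    q = q,
    significant = q <= alpha
  )
  d_cut <- if (any(result$significant)) {
    min(abs(result$d_stat[result$significant]))
  } else {
    NA_real_
  }
  structure(
    list(
      result = result,
      s0 = s0, alpha = alpha, df = obs$df,
      n_perm = n_used, exhaustive = perms$exhaustive,
      groups = c(group_a, group_b),
      n_a = length(idx_a), n_b = length(idx_b),
      d_cut = d_cut
    ),
    class = "trex_enrichment"
  )
}

#' @export
print.trex_enrichment <- function(x, ...) {
  cat(sprintf(
    "<trex_enrichment> %s vs %s (%d vs %d): %d proteins, %d significant at FDR %.3g (S0 = %.3g, %d %s permutations)\n",
    x$groups[1], x$groups[2], x$n_a, x$n_b, nrow(x$result),
    sum(x$result$significant), x$alpha, x$s0, x$n_perm,
    if (x$exhaustive) "exhaustive" else "random"
  ))
  invisible(x)
}

#' @describeIn permutation_fdr Per-protein results as a tibble.
#' @param x A `trex_enrichment` object.
#' @param ... Unused.
#' @method tidy trex_enrichment
#' @export
tidy.trex_enrichment <- function(x, ...) x$result

#' @describeIn permutation_fdr One-row summary (counts, settings, d cut-off).
#' @method glance trex_enrichment
#' @export
glance.trex_enrichment <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$result),
    n_significant = sum(x$result$significant),
    s0 = x$s0,
    alpha = x$alpha,
    n_perm = x$n_perm,
    exhaustive = x$exhaustive,
    d_cut = x$d_cut,
    df = x$df
  )
}

#' Volcano significance boundary
#'
#' Traces the hyperbolic curve separating significant from non-significant
#' points on a volcano plot of log2 difference versus -log10 p. A point with
#' absolute difference `x` and two-sided p value `p` implies a standard
#' error `x / t(p)`; it reaches the moderated cut-off `d_cut` when
#' `x / (x / t + s0) >= d_cut`, i.e. above the curve
#' `p(x) = 2 * pt(-x / (x / d_cut - s0), df)`, defined for
#' `x > s0 * d_cut`. With `s0 = 0` the boundary is the horizontal line at
#' the p value of `d_cut` itself.
#'
#' @param s0 Artificial within-groups standard deviation.
#' @param d_cut Moderated-statistic cut-off, e.g. `glance(fit)$d_cut` from
#'   [permutation_fdr()] (the smallest `|d|` among significant proteins).
#' @param df Degrees of freedom of the underlying t approximation.
#' @param diff_grid Numeric grid of absolute differences to evaluate.
#' @return Tibble with `difference` (both signs) and `neg_log10_p`; `NA`
#'   where no p value reaches significance (|difference| <= s0 * d_cut).
#' @export
significance_boundary <- function(s0, d_cut, df, diff_grid) {
  check_scalar_number(d_cut, "d_cut", min = 0, strict_min = TRUE)
  check_scalar_number(s0, "s0", min = 0)
  if (length(diff_grid) == 0L) {
    return(tibble::tibble(difference = numeric(), neg_log10_p = numeric()))
  }
  x <- abs(diff_grid)
  t_req <- ifelse(x > s0 * d_cut, x / (x / d_cut - s0), NA_real_)
  nlp <- -log10(2 * pt(-t_req, df = df))
  tibble::tibble(
    difference = c(-rev(x), x),
    neg_log10_p = c(rev(nlp), nlp)
  )
}

#' PCA-based replicate QC
#'
#' Principal component analysis of the centered sample x protein matrix
#' (transformed, imputation-complete data). A replicate is flagged as a
#' candidate outlier when its distance to its own group centroid in the
#' first two components exceeds `flag_factor` times the median within-group
#' centroid distance. Flags are advisory — removal is the analyst's call.
#'
#' @param tbl Imputation-complete wide tibble of log2 intensities.
#' @param samples Sample sheet.
#' @param flag_factor Flagging multiple of the median centroid distance
#'   (default 3).
#' @param id_col Name of the id column.
#' @return A list of class `trex_pca` with `coordinates` (tibble:
#'   `sample_id`, `group`, `pc1`, `pc2`, `centroid_distance`, `flagged`)
#'   and `variance_fraction` (per component).
#' @export
pca_qc <- function(tbl, samples, flag_factor = 3, id_col = "protein_id") {
  samples <- check_samples(samples)
  m <- quant_matrix(tbl, id_col)
  if (anyNA(m)) abort("Impute missing values before PCA.")
  idx <- group_columns(m, samples)
  if (ncol(m) < 3L) abort("PCA QC needs at least 3 samples.")
  x <- t(m)[samples$sample_id, , drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- tibble::tibble(
    sample_id = rownames(pc$x),
    group = samples$group[match(rownames(pc$x), samples$sample_id)],
    pc1 = pc$x[, 1],
    pc2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0
  )
  coords <- coords |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      centroid_distance = sqrt(
        (.data$pc1 - mean(.data$pc1))^2 + (.data$pc2 - mean(.data$pc2))^2
      )
    ) |>
    dplyr::ungroup()
  med <- median(coords$centroid_distance)
  coords$flagged <- coords$centroid_distance > flag_factor * med
  structure(
    list(coordinates = coords, variance_fraction = var_frac),
    class = "trex_pca"
  )
}

#' @export
print.trex_pca <- function(x, ...) {
  cat(sprintf(
    "<trex_pca> %d samples; PC1 %.1f%%, PC2 %.1f%% of variance; %d flagged\n",
    nrow(x$coordinates), 100 * x$variance_fraction[1],
    100 * (x$variance_fraction[2] %||% 0), sum(x$coordinates$flagged)
  ))
  invisible(x)
}

#' @describeIn pca_qc Sample coordinates and flags as a tibble.
#' @param x A `trex_pca` object.
#' @param ... Unused.
#' @method tidy trex_pca
#' @export
tidy.trex_pca <- function(x, ...) x$coordinates

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (a validating wrapper around
#' `p.adjust(..., method = "BH")`).
#'
#' @param pvals Numeric vector of p values in \[0, 1\].
#' @return Adjusted q values, monotone in p and capped at 1.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("All p values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' One-call TREX enrichment pipeline
#'
#' Convenience wrapper chaining the canonical order of operations on a raw
#' (linear-scale) intensity table: log2 transform, minimum-valid filter,
#' Gaussian downshift imputation, S0-moderated test with permutation FDR.
#'
#' @inheritParams permutation_fdr
#' @inheritParams impute_gaussian_downshift
#' @inheritParams filter_min_valid
#' @param tbl Wide tibble of linear-scale intensities (`NA` = missing).
#' @return A `trex_enrichment` object (see [permutation_fdr()]).
#' @export
trex_enrich <- function(tbl, samples, group_a = "plus_rnaseh",
                        group_b = "minus_rnaseh", s0 = 0.1, alpha = 0.05,
                        n_perm = 250, min_valid = 3, downshift = 1.8,
                        width = 0.3, seed = NULL, id_col = "protein_id") {
  samples <- check_samples(samples)
  samples <- samples[samples$group %in% c(group_a, group_b), ]
  keep <- c(id_col, samples$sample_id)
  tbl[intersect(names(tbl), keep)] |>
    log2_transform(id_col = id_col) |>
    filter_min_valid(samples, min_valid = min_valid, id_col = id_col) |>
    impute_gaussian_downshift(
      downshift = downshift, width = width, seed = seed, id_col = id_col
    ) |>
    permutation_fdr(
      samples, group_a = group_a, group_b = group_b, s0 = s0,
      alpha = alpha, n_perm = n_perm, seed = seed, id_col = id_col
    )
}
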