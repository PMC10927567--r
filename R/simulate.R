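# Synthetic TREX experiments with planted ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# per-protein baseline log2 abundances, a released subpopulation whose
# +RNase H eluate intensity rises by a planted log2 effect, replicate noise,
# intensity-dependent (left-censored, missing-not-at-random) missingness,
# iBAQ columns derived from peptide counts, and matched total-proteome
# samples. TREX eluates are modelled as released material: the -RNase H
# control recovers a small background fraction b of every protein, the
# +RNase H eluate recovers b plus the bound fraction f of released
# proteins, so the planted log2 group difference is delta = log2(1 + f/b)
# and the affinity module's Ka recovers f directly.

#' Configuration for a simulated TREX experiment
#'
#' Defaults describe a routine TREX run: 1,000 background proteins, 50
#' released proteins, 5 biological replicates per group, log2 baseline
#' abundances Normal(25, 2), replicate noise s.d. 0.3, a mean release
#' effect of 2 log2 units (4-fold) spread uniformly over 1 to 4 log2 units
#' across released proteins (bound fractions spanning roughly 0.05-0.75,
#' matching the orders-of-magnitude spread of ranked interactor affinities),
#' background release fraction 0.05,
#' and logistic left-censoring with midpoint at the 15th percentile of the
#' simulated intensities.
#'
#' @param n_background,n_released Numbers of background and released
#'   proteins.
#' @param n_rep Replicates per group (applies to `plus_rnaseh`,
#'   `minus_rnaseh` and `total`).
#' @param base_mean,base_sd Mean and s.d. of the per-protein baseline log2
#'   intensity.
#' @param delta Mean planted release effect in log2 units (difference
#'   between +RNase H and -RNase H group means for released proteins).
#' @param delta_jitter Released proteins draw their effect uniformly from
#'   `delta * [1 - delta_jitter/2, 1 + delta_jitter]`, giving a spread of
#'   true bound fractions.
#' @param noise_sd Replicate noise s.d. in log2 units.
#' @param background_frac Background release fraction `b` common to both
#'   TREX groups.
#' @param censor_quantile Quantile of the simulated intensities at which
#'   the missingness probability is 0.5 (default 0.15).
#' @param censor_slope Logistic slope of missingness in log2 units.
#' @param peptide_range Range of observable-peptide counts drawn per
#'   protein.
#' @return A list of class `trex_sim_config`.
#' @export
trex_sim_config <- function(n_background = 1000, n_released = 50,
                            n_rep = 5, base_mean = 25, base_sd = 2,
                            delta = 2, delta_jitter = 1, noise_sd = 0.3,
                            background_frac = 0.05, censor_quantile = 0.15,
                            censor_slope = 0.7, peptide_range = c(5, 40)) {
  check_scalar_number(n_background, "n_background", min = 1)
  check_scalar_number(n_released, "n_released", min = 0)
  check_scalar_number(n_rep, "n_rep", min = 2)
  check_scalar_number(base_sd, "base_sd", min = 0, strict_min = TRUE)
  check_scalar_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE)
  check_scalar_number(delta, "delta", min = 0)
  check_scalar_number(background_frac, "background_frac", min = 0,
                      strict_min = TRUE)
  check_scalar_number(censor_quantile, "censor_quantile", min = 0, max = 1)
  check_scalar_number(censor_slope, "censor_slope", min = 0,
                      strict_min = TRUE)
  structure(
    list(
      n_background = as.integer(n_background),
      n_released = as.integer(n_released),
      n_rep = as.integer(n_rep),
      base_mean = base_mean, base_sd = base_sd,
      delta = delta, delta_jitter = delta_jitter, noise_sd = noise_sd,
      background_frac = background_frac,
      censor_quantile = censor_quantile, censor_slope = censor_slope,
      peptide_range = as.integer(peptide_range)
    ),
    class = "trex_sim_config"
  )
}

# Left-censoring probability for a log2 intensity given the logistic
# midpoint and slope: decreasing in intensity.
censor_probability <- function(value, midpoint, slope) {
  stats::plogis((midpoint - value) / slope)
}

#' Simulate a TREX label-free proteomics experiment
#'
#' See [trex_sim_config()] for the generative model. Deterministic given
#' the seed: the same seed yields byte-identical tables.
#'
#' @param cfg A [trex_sim_config()].
#' @param seed Integer seed.
#' @return List with `quant` (a [trex_quant] with intensity and iBAQ
#'   tables; `NA` marks censored cells) and `truth` (tibble: `protein_id`,
#'   `released`, `true_delta` in log2 units, `true_bound_fraction`,
#'   `peptide_count`, `baseline`).
#' @export
simulate_trex <- function(cfg = trex_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "trex_sim_config"))
  with_seed_or_not(seed, {
    n <- cfg$n_background + cfg$n_released
    ids <- sprintf("P%05d", seq_len(n))
    released <- c(rep(FALSE, cfg$n_background), rep(TRUE, cfg$n_released))
    if (cfg$delta == 0) released[] <- FALSE  # no effect, no released set
    delta_i <- ifelse(
      released,
      cfg$delta * runif(n, 1 - cfg$delta_jitter / 2, 1 + cfg$delta_jitter),
      0
    )
    b <- cfg$background_frac
    bound_frac <- ifelse(released, pmin(b * (2^delta_i - 1), 1), 0)
    delta_i <- ifelse(released, log2(1 + bound_frac / b), 0)
    mu <- rnorm(n, cfg$base_mean, cfg$base_sd)
    peptide_count <- sample(
      seq(cfg$peptide_range[1], cfg$peptide_range[2]), n, replace = TRUE
    )
    groups <- c("plus_rnaseh", "minus_rnaseh", "total")
    samples <- tibble::tibble(
      sample_id = paste0(
        rep(c("plus", "minus", "total"), each = cfg$n_rep), "_",
        rep(seq_len(cfg$n_rep), times = 3)
      ),
      group = rep(groups, each = cfg$n_rep),
      replicate = rep(seq_len(cfg$n_rep), times = 3)
    )
    group_mean <- cbind(
      plus_rnaseh = mu + log2(b + bound_frac),
      minus_rnaseh = mu + log2(b),
      total = mu
    )
    value <- matrix(NA_real_, n, nrow(samples),
                    dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      value[, j] <- group_mean[, samples$group[j]] +
        rnorm(n, 0, cfg$noise_sd)
    }
    midpoint <- quantile(value, cfg$censor_quantile, names = FALSE)
    miss <- matrix(
      runif(length(value)) <
        censor_probability(value, midpoint, cfg$censor_slope),
      nrow = n
    )
    intensity <- 2^value
    intensity[miss] <- NA_real_
    ibaq <- intensity / peptide_count
    quant <- trex_quant(
      matrix_to_tbl(intensity), samples,
      ibaq = matrix_to_tbl(ibaq)
    )
    truth <- tibble::tibble(
      protein_id = ids,
      released = released,
      true_delta = delta_i,
      true_bound_fraction = bound_frac,
      peptide_count = peptide_count,
      baseline = mu
    )
    list(quant = quant, truth = truth, censor_midpoint = midpoint)
  })
}

#' Simulate a multi-region TREX design
#'
#' Emulates region-by-region TREX along one long transcript: a shared
#' background proteome, region-specific binders released in exactly one
#' region's +RNase H group, and multiregional binders released in at least
#' `multiregion_min` regions with independent effects.
#'
#' @param cfg A [trex_sim_config()]; `n_released` is the total number of
#'   planted binders across regions.
#' @param regions Character vector of region names (>= 2).
#' @param fraction_multiregional Fraction of planted binders that are
#'   multiregional (default 0.05).
#' @param multiregion_min Minimum number of regions a multiregional binder
#'   occupies (default 3).
#' @param seed Integer seed.
#' @return List with `quants` (named list of [trex_quant], one per region)
#'   and `truth` (tibble: `protein_id`, `binder`, `multiregional`,
#'   `regions` list-column of release regions, `primary_region`).
#' @export
simulate_multiregion <- function(cfg = trex_sim_config(n_released = 120),
                                 regions = paste0("region_", 1:8),
                                 fraction_multiregional = 0.05,
                                 multiregion_min = 3, seed = 1) {
  stopifnot(inherits(cfg, "trex_sim_config"))
  if (length(regions) < 2L) abort("At least 2 regions are required.")
  if (anyDuplicated(regions)) abort("Region names must be unique.")
  check_scalar_number(fraction_multiregional, "fraction_multiregional",
                      min = 0, max = 1)
  if (multiregion_min > length(regions)) {
    abort("`multiregion_min` exceeds the number of regions.")
  }
  with_seed_or_not(seed, {
    n <- cfg$n_background + cfg$n_released
    ids <- sprintf("P%05d", seq_len(n))
    binder <- c(rep(FALSE, cfg$n_background), rep(TRUE, cfg$n_released))
    multi <- binder & (runif(n) < fraction_multiregional)
    region_sets <- vector("list", n)
    for (i in which(binder)) {
      region_sets[[i]] <- if (multi[i]) {
        k <- sample(seq(multiregion_min, length(regions)), 1)
        sample(regions, k)
      } else {
        sample(regions, 1)
      }
    }
    mu <- rnorm(n, cfg$base_mean, cfg$base_sd)
    quants <- list()
    sub_seeds <- sample.int(.Machine$integer.max, length(regions))
    for (r in seq_along(regions)) {
      rg <- regions[r]
      rel_here <- vapply(
        region_sets, function(s) !is.null(s) && rg %in% s, logical(1)
      )
      # reuse the single-region generator machinery on a per-region basis:
      # released set and shared baselines are imposed below
      sim <- simulate_trex_given(
        cfg, ids, rel_here, mu, seed = sub_seeds[r]
      )
      quants[[rg]] <- sim$quant
    }
    truth <- tibble::tibble(
      protein_id = ids,
      binder = binder,
      multiregional = multi,
      regions = region_sets,
      primary_region = purrr::map_chr(
        region_sets, ~ if (is.null(.x)) NA_character_ else .x[[1]]
      )
    )
    list(quants = quants, truth = truth)
  })
}

# Single-region table with externally imposed ids, released mask and shared
# baselines (used by the multi-region generator).
simulate_trex_given <- function(cfg, ids, released, mu, seed) {
  with_seed_or_not(seed, {
    n <- length(ids)
    delta_i <- ifelse(
      released,
      cfg$delta * runif(n, 1 - cfg$delta_jitter / 2, 1 + cfg$delta_jitter),
      0
    )
    b <- cfg$background_frac
    bound_frac <- ifelse(released, pmin(b * (2^delta_i - 1), 1), 0)
    samples <- tibble::tibble(
      sample_id = paste0(
        rep(c("plus", "minus"), each = cfg$n_rep), "_",
        rep(seq_len(cfg$n_rep), times = 2)
      ),
      group = rep(c("plus_rnaseh", "minus_rnaseh"), each = cfg$n_rep),
      replicate = rep(seq_len(cfg$n_rep), times = 2)
    )
    group_mean <- cbind(
      plus_rnaseh = mu + log2(b + bound_frac),
      minus_rnaseh = mu + log2(b)
    )
    value <- matrix(NA_real_, n, nrow(samples),
                    dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      value[, j] <- group_mean[, samples$group[j]] + rnorm(n, 0, cfg$noise_sd)
    }
    midpoint <- quantile(value, cfg$censor_quantile, names = FALSE)
    miss <- matrix(
      runif(length(value)) <
        censor_probability(value, midpoint, cfg$censor_slope),
      nrow = n
    )
    intensity <- 2^value
    intensity[miss] <- NA_real_
    list(quant = trex_quant(matrix_to_tbl(intensity), samples))
  })
}

#' Simulate a TPM table with planted depletions
#'
#' Log-normal transcript abundances (log2 TPM ~ Normal(`log2_mean`,
#' `log2_sd`)), identical in both groups except for the planted depleted
#' transcripts, whose treated-group TPM is divided by their fold change.
#'
#' @param n_transcripts Number of transcripts.
#' @param depleted_folds Named numeric vector: names are depleted
#'   transcript indices or ids, values are fold depletions (>= 1).
#' @param n_rep Replicates per group (default 3).
#' @param log2_mean,log2_sd Baseline log2 TPM distribution.
#' @param noise_sd Replicate noise s.d. in log2 units.
#' @param seed Integer seed.
#' @return List with `tpm` (wide tibble: `transcript_id` + samples),
#'   `samples` sheet (groups `rnaseh` / `control`) and `truth`.
#' @export
simulate_tpm <- function(n_transcripts = 5000, depleted_folds = numeric(),
                         n_rep = 3, log2_mean = 4, log2_sd = 2,
                         noise_sd = 0.25, seed = 1) {
  check_scalar_number(n_transcripts, "n_transcripts", min = 2)
  if (length(depleted_folds) > 0 && any(depleted_folds < 1)) {
    abort("Depletion fold changes must be >= 1.")
  }
  with_seed_or_not(seed, {
    ids <- sprintf("TX%05d", seq_len(n_transcripts))
    dep_ids <- if (length(depleted_folds) == 0) {
      character()
    } else if (is.null(names(depleted_folds))) {
      ids[seq_along(depleted_folds)]
    } else {
      names(depleted_folds)
    }
    if (!all(dep_ids %in% ids)) abort("Unknown depleted transcript id(s).")
    base <- rnorm(n_transcripts, log2_mean, log2_sd)
    fold <- setNames(rep(1, n_transcripts), ids)
    fold[dep_ids] <- as.numeric(depleted_folds)
    samples <- tibble::tibble(
      sample_id = paste0(
        rep(c("rnaseh", "control"), each = n_rep), "_",
        rep(seq_len(n_rep), times = 2)
      ),
      group = rep(c("rnaseh", "control"), each = n_rep),
      replicate = rep(seq_len(n_rep), times = 2)
    )
    value <- matrix(NA_real_, n_transcripts, nrow(samples),
                    dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      shift <- if (samples$group[j] == "rnaseh") -log2(fold) else 0
      value[, j] <- base + shift + rnorm(n_transcripts, 0, noise_sd)
    }
    tpm <- matrix_to_tbl(2^value, id_col = "transcript_id")
    truth <- tibble::tibble(
      transcript_id = ids,
      depleted = ids %in% dep_ids,
      fold = unname(fold)
    )
    list(tpm = tpm, samples = samples, truth = truth)
  })
}

#' Simulate a qPCR Ct table
#'
#' `ct_target = mean(housekeeping Ct) - log2(level) + noise`, so
#' [relative_expression()] recovers the planted levels exactly at zero
#' noise. Housekeeping wells receive the same measurement noise.
#'
#' @param levels Named list (sample_id -> named numeric vector of true
#'   relative levels per target, all > 0).
#' @param housekeeping_ct Named numeric vector of true housekeeping Cts
#'   (e.g. `c(GAPDH = 20, RPS18 = 18)`).
#' @param noise_sd Ct measurement noise s.d. in cycles (default 0.1).
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `target`, `ct`, `housekeeping`.
#' @export
simulate_qpcr <- function(levels, housekeeping_ct = c(GAPDH = 20, RPS18 = 18),
                          noise_sd = 0.1, seed = 1) {
  if (length(levels) == 0L || is.null(names(levels))) {
    abort("`levels` must be a named list of per-sample level vectors.")
  }
  if (length(housekeeping_ct) == 0L || is.null(names(housekeeping_ct))) {
    abort("`housekeeping_ct` must be a named numeric vector.")
  }
  with_seed_or_not(seed, {
    rows <- purrr::imap(levels, function(lv, sid) {
      if (any(lv <= 0)) abort("True relative levels must be positive.")
      if (is.null(names(lv))) names(lv) <- paste0("target_", seq_along(lv))
      hk_mean <- mean(housekeeping_ct)
      dplyr::bind_rows(
        tibble::tibble(
          sample_id = sid,
          target = names(housekeeping_ct),
          ct = unname(housekeeping_ct) + rnorm(length(housekeeping_ct), 0,
                                               noise_sd),
          housekeeping = TRUE
        ),
        tibble::tibble(
          sample_id = sid,
          target = names(lv),
          ct = hk_mean - log2(unname(lv)) + rnorm(length(lv), 0, noise_sd),
          housekeeping = FALSE
        )
      )
    })
    dplyr::bind_rows(rows)
  })
}
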