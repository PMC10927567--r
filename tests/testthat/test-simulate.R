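test_that("simulators are pure functions of config and seed", {
  cfg <- trex_sim_config(n_background = 60, n_released = 6)
  s1 <- simulate_trex(cfg, seed = 5)
  s2 <- simulate_trex(cfg, seed = 5)
  s3 <- simulate_trex(cfg, seed = 6)
  expect_identical(s1$quant$intensity, s2$quant$intensity)
  expect_identical(s1$quant$ibaq, s2$quant$ibaq)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$quant$intensity, s3$quant$intensity))
  t1 <- simulate_tpm(n_transcripts = 50, seed = 2)
  t2 <- simulate_tpm(n_transcripts = 50, seed = 2)
  expect_identical(t1$tpm, t2$tpm)
  q1 <- simulate_qpcr(list(s1 = c(U1 = 0.25)), seed = 3)
  q2 <- simulate_qpcr(list(s1 = c(U1 = 0.25)), seed = 3)
  expect_identical(q1, q2)
})

test_that("zero release effect empties the ground-truth released set", {
  sim <- simulate_trex(trex_sim_config(n_background = 200, n_released = 20,
                                       delta = 0), seed = 4)
  expect_equal(sum(sim$truth$released), 0L)
  expect_true(all(sim$truth$true_bound_fraction == 0))
})

test_that("missingness is left-censored: decreasing in intensity decile", {
  # the censoring law itself is monotone
  p <- censor_prob <- trexkit:::censor_probability(seq(10, 30, 0.5), 20, 0.7)
  expect_true(all(diff(p) < 0))
  # realized missingness concentrates at low abundance
  sim <- simulate_trex(trex_sim_config(n_background = 4000, n_released = 0,
                                       delta = 0), seed = 9)
  m <- as.matrix(sim$quant$intensity[-1])
  base <- sim$truth$baseline
  decile <- cut(base, quantile(base, 0:10 / 10), include.lowest = TRUE,
                labels = FALSE)
  miss_rate <- tapply(rowMeans(is.na(m)), decile, mean)
  expect_lt(miss_rate[10], miss_rate[1])
  expect_lt(mean(diff(miss_rate) > 0), 0.25)  # near-monotone decrease
})

test_that("planted effects land where the model says they should", {
  cfg <- trex_sim_config(n_background = 300, n_released = 40)
  sim <- simulate_trex(cfg, seed = 10)
  tr <- sim$truth
  expect_equal(tr$true_delta[tr$released],
               log2(1 + tr$true_bound_fraction[tr$released] /
                      cfg$background_frac))
  # group mean differences track the planted delta
  long <- tidy(sim$quant)
  sub <- long[long$group != "total" & !is.na(long$intensity), ]
  mm <- tapply(log2(sub$intensity), list(sub$protein_id, sub$group), mean)
  diffs <- mm[, "plus_rnaseh"] - mm[, "minus_rnaseh"]
  rel_delta <- setNames(tr$true_delta, tr$protein_id)[tr$released]
  rel_delta <- rel_delta[names(rel_delta) %in%
                           names(diffs)[!is.na(diffs)]]
  expect_gt(cor(diffs[names(rel_delta)], rel_delta), 0.9)
  # iBAQ = intensity / peptide count, linear scale
  expect_equal(
    as.matrix(sim$quant$ibaq[-1]),
    as.matrix(sim$quant$intensity[-1]) / tr$peptide_count
  )
})

test_that("generated tables satisfy the pipeline preconditions", {
  sim <- simulate_trex(trex_sim_config(n_background = 150, n_released = 15),
                       seed = 20)
  m <- as.matrix(sim$quant$intensity[-1])
  expect_true(all(m > 0, na.rm = TRUE))     # log2-transformable
  expect_true(all(colSums(!is.na(m)) >= 2)) # imputable columns
  expect_silent(
    fit <- trex_enrich(sim$quant$intensity, sim$quant$samples,
                       n_perm = 50, seed = 21)
  )
  expect_s3_class(fit, "trex_enrichment")
})

test_that("multiregion truth is consistent with the per-region tables", {
  sim <- simulate_multiregion(
    trex_sim_config(n_background = 150, n_released = 30),
    regions = paste0("r", 1:4), fraction_multiregional = 0.2,
    multiregion_min = 3, seed = 30
  )
  expect_named(sim$quants, paste0("r", 1:4))
  tr <- sim$truth
  expect_true(all(lengths(tr$regions[tr$binder]) >= 1))
  expect_true(all(lengths(tr$regions[tr$multiregional]) >= 3))
  expect_true(all(lengths(tr$regions[tr$binder & !tr$multiregional]) == 1))
  # same truth structure, different noise under another seed
  sim2 <- simulate_multiregion(
    trex_sim_config(n_background = 150, n_released = 30),
    regions = paste0("r", 1:4), fraction_multiregional = 0.2,
    multiregion_min = 3, seed = 30
  )
  expect_identical(sim$truth, sim2$truth)
  expect_error(
    simulate_multiregion(regions = "one", seed = 1), "2 regions"
  )
})

test_that("qPCR simulator round-trips levels through 2^-dCT", {
  levels <- list(ctrl = c(U1 = 1, NORAD = 0.5), dep = c(U1 = 0.05,
                                                        NORAD = 4))
  ct <- simulate_qpcr(levels, noise_sd = 0, seed = 1)
  out <- qpcr_relative_expression(ct)
  for (s in names(levels)) {
    got <- out$relative_expression[out$sample_id == s]
    names(got) <- out$target[out$sample_id == s]
    expect_equal(got[names(levels[[s]])], levels[[s]])
  }
  expect_error(simulate_qpcr(list(a = c(x = -1))), "positive")
})

test_that("TPM simulator plants fold depletions where asked", {
  sim <- simulate_tpm(n_transcripts = 400,
                      depleted_folds = c(TX00010 = 16), noise_sd = 0.05,
                      seed = 40)
  m <- as.matrix(sim$tpm[-1])
  rown <- sim$tpm$transcript_id
  treated <- grepl("^rnaseh", colnames(m))
  lfc <- log2(rowMeans(m[, !treated]) / rowMeans(m[, treated]))
  expect_lt(abs(lfc[rown == "TX00010"] - 4), 0.3)
  expect_lt(max(abs(lfc[rown != "TX00010"])), 1)
  expect_error(simulate_tpm(depleted_folds = c(TX00001 = 0.5)), ">= 1")
})
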