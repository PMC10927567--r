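test_that("log2 transform maps values, keeps missing, rejects zeros", {
  tbl <- make_wide(matrix(c(8, NA, 1, 2), 2,
                          dimnames = list(NULL, c("s1", "s2"))))
  out <- log2_transform(tbl)
  expect_equal(out$s1, c(3, NA))
  expect_equal(out$s2, c(0, 1))
  bad <- tbl
  bad$s1[2] <- 0
  expect_error(log2_transform(bad), "missing")
})

test_that("minimum-valid filter keeps rows with enough values in one group", {
  samples <- make_samples(5, 5)
  m <- matrix(rnorm(40, 20), 4, 10)
  m[1, 6:10] <- NA          # 5 in A, 0 in B -> kept
  m[2, ] <- NA              # all missing -> dropped
  m[3, c(3:5, 8:10)] <- NA  # 2 in A, 2 in B -> dropped
  m[4, c(1, 2, 6, 7)] <- NA # 3 in A, 3 in B -> kept
  colnames(m) <- samples$sample_id
  out <- filter_min_valid(make_wide(m), samples, min_valid = 3)
  expect_equal(out$protein_id, c("P001", "P004"))
  expect_error(filter_min_valid(make_wide(m), samples, min_valid = 6),
               "exceeds")
})

test_that("downshift imputation draws from the shifted Gaussian", {
  samples <- make_samples(2, 2)
  # exact column moments: present values 20 +- sqrt(2) -> mean 20, sd 2
  m <- matrix(rnorm(4 * 4, 20, 1), 4, 4,
              dimnames = list(NULL, samples$sample_id))
  full <- make_wide(m)
  expect_identical(impute_gaussian_downshift(full, seed = 1), full)
  col <- c(20 - sqrt(2), 20 + sqrt(2), rep(NA_real_, 3000))
  tbl <- make_wide(cbind(s1 = col, s2 = rep(21, length(col))))
  imp <- impute_gaussian_downshift(tbl, seed = 9)
  drawn <- imp$s1[-(1:2)]
  expect_lt(abs(mean(drawn) - (20 - 1.8 * 2)), 0.1)
  expect_lt(abs(sd(drawn) - 0.6), 0.05)
  # untouched present cells, determinism, missing-mask containment
  expect_identical(imp$s1[1:2], col[1:2])
  expect_identical(imp, impute_gaussian_downshift(tbl, seed = 9))
  expect_false(identical(imp, impute_gaussian_downshift(tbl, seed = 10)))
  expect_error(
    impute_gaussian_downshift(
      make_wide(cbind(s1 = c(1, NA, NA), s2 = c(1, 2, 3)))
    ),
    "fewer than 2"
  )
})

test_that("S0 statistic reduces to Student t at s0 = 0 and damps small diffs", {
  set.seed(21)
  for (i in 1:10) {
    xa <- rnorm(5, 1)
    xb <- rnorm(7)
    res <- two_sample_s0_test(xa, xb, s0 = 0)
    expect_equal(res$d_stat, oracle_pooled_t(xa, xb))
    tt <- t.test(xa, xb, var.equal = TRUE)
    expect_equal(res$d_stat, unname(tt$statistic))
    expect_equal(res$p, tt$p.value)
  }
  x <- rnorm(4)
  same <- two_sample_s0_test(x, x)
  expect_equal(same$difference, 0)
  expect_equal(same$d_stat, 0)
  expect_equal(same$p, 1)
  # |d| decreases monotonically toward 0 as s0 grows
  xa <- rnorm(4, 2)
  xb <- rnorm(4)
  ds <- vapply(c(0, 0.1, 1, 10, 1000),
               function(s0) abs(two_sample_s0_test(xa, xb, s0)$d_stat),
               numeric(1))
  expect_true(all(diff(ds) < 0))
  expect_lt(ds[length(ds)], 1e-2)
  expect_error(two_sample_s0_test(1, rnorm(3)), "at least 2")
})

test_that("exhaustive permutation FDR equals the brute-force oracle", {
  set.seed(31)
  m <- matrix(rnorm(20 * 6, 20), 20, 6)
  m[1:3, 1:3] <- m[1:3, 1:3] + 4  # a few real effects
  samples <- make_samples(3, 3)
  colnames(m) <- samples$sample_id
  fit <- permutation_fdr(make_wide(m), samples, n_perm = 20)  # all C(6,3)=20
  expect_true(fit$exhaustive)
  q_oracle <- oracle_perm_fdr(m, 1:3, 4:6, s0 = 0.1)
  expect_equal(tidy(fit)$q, q_oracle)
  expect_true(all(tidy(fit)$significant == (q_oracle <= 0.05)))
  # d sign matches difference sign; q in [0, 1]
  res <- tidy(fit)
  expect_true(all(sign(res$d_stat) == sign(res$difference)))
  expect_true(all(res$q >= 0 & res$q <= 1))
})

test_that("random-split permutation FDR is seed-deterministic", {
  set.seed(41)
  samples <- make_samples(5, 5)
  m <- matrix(rnorm(200 * 10, 20), 200, 10,
              dimnames = list(NULL, samples$sample_id))
  tbl <- make_wide(m)
  f1 <- permutation_fdr(tbl, samples, n_perm = 50, seed = 3)
  f2 <- permutation_fdr(tbl, samples, n_perm = 50, seed = 3)
  f3 <- permutation_fdr(tbl, samples, n_perm = 50, seed = 4)
  expect_false(f1$exhaustive)
  expect_identical(tidy(f1), tidy(f2))
  expect_false(identical(tidy(f1)$q, tidy(f3)$q))
})

test_that("significance boundary is hyperbolic, symmetric and monotone", {
  grid <- seq(0.01, 6, by = 0.01)
  b <- significance_boundary(s0 = 0.1, d_cut = 3, df = 8, diff_grid = grid)
  pos <- b[b$difference > 0, ]
  neg <- b[b$difference < 0, ]
  expect_equal(pos$neg_log10_p, rev(neg$neg_log10_p))
  # undefined below the s0 * d_cut asymptote, non-increasing beyond it
  expect_true(all(is.na(pos$neg_log10_p[pos$difference <= 0.3])))
  defined <- pos$neg_log10_p[!is.na(pos$neg_log10_p)]
  expect_true(all(diff(defined) <= 0))
  # s0 = 0 -> horizontal line at the p of d_cut itself
  b0 <- significance_boundary(s0 = 0, d_cut = 3, df = 8, diff_grid = grid)
  expect_equal(unique(round(b0$neg_log10_p, 10)),
               round(-log10(2 * pt(-3, 8)), 10))
  expect_equal(
    nrow(significance_boundary(0.1, 2, 8, numeric())), 0L
  )
})

test_that("proteins at the boundary have q near alpha on matched data", {
  # calibrate a null table, then place synthetic effects on the boundary
  set.seed(51)
  samples <- make_samples(5, 5)
  m <- matrix(rnorm(800 * 10, 20, 1), 800, 10,
              dimnames = list(NULL, samples$sample_id))
  planted <- seq_len(60)
  m[planted, 1:5] <- m[planted, 1:5] + 2.5
  fit <- permutation_fdr(make_wide(m), samples, n_perm = 250, seed = 5)
  res <- tidy(fit)
  d_cut <- glance(fit)$d_cut
  near <- res[abs(abs(res$d_stat) - d_cut) < 0.3, ]
  expect_gt(nrow(near), 0)
  expect_lt(max(abs(near$q - fit$alpha)), 0.05)
})

test_that("PCA QC flags a constructed outlier replicate and only that one", {
  set.seed(61)
  samples <- make_samples(4, 4)
  m <- matrix(rnorm(300 * 8, 20, 1), 300, 8,
              dimnames = list(NULL, samples$sample_id))
  m[, 1:4] <- m[, 1:4] + 2       # group separation
  qc0 <- pca_qc(make_wide(m), samples)
  expect_false(any(qc0$coordinates$flagged))
  vf <- qc0$variance_fraction
  expect_true(all(diff(vf) <= 1e-12))
  expect_lte(sum(vf), 1 + 1e-8)
  m_out <- m
  m_out[, 3] <- m_out[, 3] + 25  # gross outlier replicate
  qc1 <- pca_qc(make_wide(m_out), samples)
  expect_identical(
    qc1$coordinates$sample_id[qc1$coordinates$flagged], "a3"
  )
  # duplicated replicates: all centroid distances zero, nothing flagged
  dup <- m[, c(1, 1, 1, 1, 5, 5, 5, 5)]
  colnames(dup) <- samples$sample_id
  qc2 <- pca_qc(make_wide(dup), samples)
  expect_false(any(qc2$coordinates$flagged))
  expect_error(pca_qc(make_wide(m[, 1:2]), samples[1:2, ]), "3 samples")
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.8))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})
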