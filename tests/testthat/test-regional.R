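# Hand-built per-region enrichment tibbles.
region_tbl <- function(ids, d, sig) {
  tibble::tibble(protein_id = ids, difference = d / 2, d_stat = d,
                 p = 0.01, q = ifelse(sig, 0.01, 0.5), significant = sig)
}

test_that("t-score matrix keeps the union of significant proteins", {
  ra <- region_tbl(c("A", "B", "C"), c(8, 1, 0.5), c(TRUE, FALSE, FALSE))
  rb <- region_tbl(c("B", "C", "D"), c(7, 2, 9), c(TRUE, FALSE, TRUE))
  rpm <- assemble_tscore_matrix(list(rA = ra, rB = rb))
  # brute-force union of per-region significant sets
  expect_setequal(rpm$proteins, union("A", c("B", "D")))
  expect_equal(rpm$tscores["A", "rA"], 8)
  expect_equal(rpm$tscores["A", "rB"], 0)    # absent -> 0 with mask
  expect_true(rpm$absent["A", "rB"])
  expect_false(rpm$absent["B", "rA"])
  expect_equal(rpm$tscores["B", "rA"], 1)    # non-significant score kept
  expect_error(assemble_tscore_matrix(list(rA = ra)), "2 regions")
  expect_error(
    assemble_tscore_matrix(setNames(list(ra, rb), c("x", "x"))), "unique"
  )
  none <- region_tbl("Z", 1, FALSE)
  expect_error(assemble_tscore_matrix(list(a = none, b = none)),
               "significant")
})

test_that("retained set and specificity are invariant to region order", {
  set.seed(81)
  ids <- sprintf("P%02d", 1:30)
  mk <- function() region_tbl(ids, rnorm(30, 3, 2), runif(30) < 0.4)
  regs <- list(r1 = mk(), r2 = mk(), r3 = mk(), r4 = mk())
  rpm_fwd <- classify_region_specificity(assemble_tscore_matrix(regs))
  rpm_rev <- classify_region_specificity(assemble_tscore_matrix(rev(regs)))
  expect_setequal(rpm_fwd$proteins, rpm_rev$proteins)
  sp_f <- rpm_fwd$specificity[order(rpm_fwd$specificity$protein_id), ]
  sp_r <- rpm_rev$specificity[order(rpm_rev$specificity$protein_id), ]
  expect_equal(sp_f$specificity, sp_r$specificity)
  expect_equal(sp_f$primary_region, sp_r$primary_region)
  # specificity classes partition the retained set
  expect_equal(
    sum(sp_f$specificity == "region_specific") +
      sum(sp_f$specificity == "multiregional"),
    length(rpm_fwd$proteins)
  )
})

test_that("specificity rule: >= 3 significant regions means multiregional", {
  ids <- c("single", "double", "multi")
  sig <- cbind(c(TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE),
               c(FALSE, FALSE, TRUE), c(FALSE, FALSE, TRUE),
               c(FALSE, FALSE, TRUE))
  regs <- purrr::map(1:5, function(r) {
    region_tbl(ids, c(1, 2, 3) + r, sig[, r])
  })
  names(regs) <- paste0("reg", 1:5)
  rpm <- classify_region_specificity(assemble_tscore_matrix(regs))
  sp <- rpm$specificity
  expect_equal(sp$specificity,
               c("region_specific", "region_specific", "multiregional"))
  # primary region is the argmax t-score (last region has largest here)
  expect_equal(sp$primary_region[1:2], c("reg5", "reg5"))
  expect_true(is.na(sp$primary_region[3]))
  expect_equal(sp$n_significant, c(1L, 2L, 5L))
})

test_that("clustering separates planted orthogonal profiles", {
  set.seed(91)
  n_half <- 20
  ids <- sprintf("P%02d", seq_len(2 * n_half))
  hotA <- c(rnorm(n_half, 12, 0.5), rnorm(n_half, 0, 0.5))
  hotB <- c(rnorm(n_half, 0, 0.5), rnorm(n_half, 12, 0.5))
  regs <- list(
    rA = region_tbl(ids, hotA, hotA > 6),
    rB = region_tbl(ids, hotB, hotB > 6)
  )
  rpm <- cluster_tscores(assemble_tscore_matrix(regs),
                         n_clusters = 2, seed = 4)
  truth <- rep(1:2, each = n_half)[match(names(rpm$clusters), ids)]
  tab <- table(truth, rpm$clusters)
  # each planted profile maps one-to-one onto a recovered cluster
  expect_equal(unname(apply(tab, 1, max)), c(n_half, n_half))
  expect_equal(length(unique(rpm$clusters)), 2L)
  # silhouette of the recovered partition is high on separated data
  sil <- cluster::silhouette(
    as.integer(rpm$clusters[rownames(rpm$tscores)]), dist(rpm$tscores)
  )
  expect_gte(mean(sil[, "sil_width"]), 0.5)
  # permuting row order recovers the same partition up to labels
  perm <- sample(length(ids))
  regs_p <- purrr::map(regs, ~ .x[perm, ])
  rpm_p <- cluster_tscores(assemble_tscore_matrix(regs_p),
                           n_clusters = 2, seed = 4)
  agree <- table(rpm$clusters[ids], rpm_p$clusters[ids])
  expect_equal(sum(agree > 0), 2L)  # one-to-one label mapping
})

test_that("clustering handles degenerate sizes and is seed-deterministic", {
  ids <- c("A", "B")
  regs <- list(
    r1 = region_tbl(ids, c(5, 0), c(TRUE, FALSE)),
    r2 = region_tbl(ids, c(0, 5), c(FALSE, TRUE))
  )
  rpm1 <- assemble_tscore_matrix(regs)
  one <- cluster_tscores(
    assemble_tscore_matrix(list(
      r1 = region_tbl("A", 5, TRUE), r2 = region_tbl("A", 1, FALSE)
    )),
    seed = 1
  )
  expect_equal(unname(one$clusters), 1L)
  expect_error(cluster_tscores(rpm1, kmeans_k = 10), "exceeds")
  c1 <- cluster_tscores(rpm1, kmeans_k = 2, seed = 2)
  c2 <- cluster_tscores(rpm1, kmeans_k = 2, seed = 2)
  expect_identical(c1$clusters, c2$clusters)
})

test_that("t-score display bins follow the fixed (0, 2, 6, 10) edges", {
  ra <- region_tbl(c("A", "B", "C", "D", "E"),
                   c(-1, 1, 4, 8, 12), rep(TRUE, 5))
  rb <- region_tbl(c("A", "B", "C", "D", "E"), rep(0, 5), rep(FALSE, 5))
  long <- tidy(assemble_tscore_matrix(list(r1 = ra, r2 = rb)))
  got <- long$bin[long$region == "r1"][match(c("A", "B", "C", "D", "E"),
                                             long$protein_id[long$region == "r1"])]
  expect_equal(as.character(got), c("<=0", "0-2", "2-6", "6-10", ">=10"))
})
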