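# Region-by-region integration: assemble the protein x region t-score
# matrix from per-region enrichment results, cluster it (k-means
# preprocessing, then complete-linkage Euclidean clustering of the
# centroids), and classify region-specific vs multiregional binders.

T_SCORE_BIN_EDGES <- c(0, 2, 6, 10)

#' Assemble a protein x region t-score matrix
#'
#' Takes one enrichment result per RNA region and keeps the union of
#' proteins significant in at least one region. Each cell holds that
#' region's moderated t statistic (`d_stat`); a protein absent from a
#' region's table contributes 0 there, with the absence recorded in a mask.
#'
#' @param results Named list (region -> [permutation_fdr()] result or its
#'   [tidy()] tibble). Names are the region order; at least 2 regions.
#' @return A list of class `trex_regional` with matrices `tscores`,
#'   `significant` and `absent` (proteins x regions), plus `regions` and
#'   `proteins`. Use [tidy()] for a long view, [autoplot()] for the binned
#'   heatmap.
#' @export
assemble_tscore_matrix <- function(results) {
  if (length(results) < 2L) abort("At least 2 regions are required.")
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("`results` must be a named list (region names).")
  }
  if (anyDuplicated(names(results))) abort("Region names must be unique.")
  tbls <- purrr::map(results, function(r) {
    if (inherits(r, "trex_enrichment")) r <- tidy(r)
    if (!all(c("protein_id", "d_stat", "significant") %in% names(r))) {
      abort("Each result needs protein_id, d_stat and significant columns.")
    }
    r
  })
  proteins <- tbls |>
    purrr::map(~ .x$protein_id[.x$significant]) |>
    purrr::reduce(union)
  if (length(proteins) == 0L) {
    abort("No protein is significant in any region.")
  }
  regions <- names(tbls)
  tscores <- matrix(0, length(proteins), length(regions),
                    dimnames = list(proteins, regions))
  sig <- matrix(FALSE, length(proteins), length(regions),
                dimnames = list(proteins, regions))
  absent <- matrix(TRUE, length(proteins), length(regions),
                   dimnames = list(proteins, regions))
  for (rg in regions) {
    tb <- tbls[[rg]]
    i <- match(tb$protein_id, proteins)
    ok <- !is.na(i)
    tscores[i[ok], rg] <- tb$d_stat[ok]
    sig[i[ok], rg] <- tb$significant[ok]
    absent[i[ok], rg] <- FALSE
  }
  structure(
    list(
      tscores = tscores, significant = sig, absent = absent,
      regions = regions, proteins = proteins,
      clusters = NULL, tree = NULL, specificity = NULL
    ),
    class = "trex_regional"
  )
}

#' Cluster regional t-score profiles
#'
#' Rows are first pre-grouped by (seeded) k-means, then the group centroids
#' are merged by complete-linkage hierarchical clustering on Euclidean
#' distances; each protein inherits its centroid's position in the tree.
#' With `n_clusters` set, the centroid tree is cut to that many final
#' clusters; otherwise each k-means group is its own cluster. Cluster ids
#' are relabelled contiguously (1, 2, ...) in tree order.
#'
#' @param rpm A `trex_regional` object from [assemble_tscore_matrix()].
#' @param kmeans_k Number of k-means pre-groups (default
#'   `min(300, floor(n/2))`, at least 1).
#' @param n_clusters Optional number of final clusters (tree cut).
#' @param seed Integer seed for k-means initialisation.
#' @return `rpm` with `clusters` (integer per protein), `tree` (the
#'   centroid `hclust`), and `protein_order` (display order: tree order of
#'   centroids, proteins within a centroid by decreasing maximum t-score).
#' @export
cluster_tscores <- function(rpm, kmeans_k = NULL, n_clusters = NULL,
                            seed = NULL) {
  stopifnot(inherits(rpm, "trex_regional"))
  n <- nrow(rpm$tscores)
  if (is.null(kmeans_k)) kmeans_k <- max(1L, min(300L, n %/% 2L))
  if (kmeans_k > n) {
    abort(sprintf("`kmeans_k` = %d exceeds the number of proteins (%d).",
                  kmeans_k, n))
  }
  if (n == 1L) {
    rpm$clusters <- setNames(1L, rpm$proteins)
    rpm$protein_order <- rpm$proteins
    return(rpm)
  }
  m <- rpm$tscores
  u <- unique(m)
  km <- if (nrow(u) <= kmeans_k) {
    # as many groups as distinct profiles: the exact k-means optimum
    key <- apply(m, 1, paste, collapse = "\r")
    list(cluster = match(key, unique(key)), centers = u)
  } else {
    with_seed_or_not(
      seed, kmeans(m, centers = kmeans_k, nstart = 5, iter.max = 100)
    )
  }
  centers <- km$centers
  if (nrow(centers) > 1L) {
    tree <- hclust(dist(centers, method = "euclidean"), method = "complete")
    center_order <- tree$order
    group_of <- if (!is.null(n_clusters)) {
      if (n_clusters > nrow(centers)) {
        abort("`n_clusters` exceeds the number of k-means groups.")
      }
      cutree(tree, k = n_clusters)
    } else {
      seq_len(nrow(centers))
    }
  } else {
    tree <- NULL
    center_order <- 1L
    group_of <- 1L
  }
  # contiguous cluster ids in tree display order
  relabel <- integer(length(unique(group_of)))
  nxt <- 0L
  for (ct in center_order) {
    g <- group_of[ct]
    if (relabel[g] == 0L) {
      nxt <- nxt + 1L
      relabel[g] <- nxt
    }
  }
  clusters <- relabel[group_of[km$cluster]]
  names(clusters) <- rpm$proteins
  row_strength <- apply(rpm$tscores, 1, max)
  protein_order <- unlist(lapply(center_order, function(ct) {
    members <- which(km$cluster == ct)
    rpm$proteins[members[order(-row_strength[members])]]
  }))
  rpm$clusters <- clusters
  rpm$tree <- tree
  rpm$protein_order <- protein_order
  rpm
}

#' Classify region-specific versus multiregional binders
#'
#' A protein significant in at least `multiregion_min` regions is called
#' multiregional; otherwise it is region-specific with its primary region
#' the one with the largest t-score (ties broken by region order). The
#' default of 3 keeps binders straddling a junction between two adjacent
#' regions classified as region-specific.
#'
#' @param rpm A `trex_regional` object.
#' @param multiregion_min Minimum number of significant regions for a
#'   multiregional call (default 3).
#' @return `rpm` with a `specificity` tibble: `protein_id`, `n_significant`,
#'   `specificity` (`"region_specific"` / `"multiregional"`),
#'   `primary_region` (`NA` for multiregional), `tie` (whether the argmax
#'   was tied).
#' @export
classify_region_specificity <- function(rpm, multiregion_min = 3) {
  stopifnot(inherits(rpm, "trex_regional"))
  n_sig <- rowSums(rpm$significant)
  best <- apply(rpm$tscores, 1, function(x) which.max(x))  # first max on ties
  tie <- apply(rpm$tscores, 1, function(x) sum(x == max(x)) > 1L)
  multi <- n_sig >= multiregion_min
  rpm$specificity <- tibble::tibble(
    protein_id = rpm$proteins,
    n_significant = unname(as.integer(n_sig)),
    specificity = unname(ifelse(multi, "multiregional", "region_specific")),
    primary_region = unname(
      ifelse(multi, NA_character_, rpm$regions[best])
    ),
    tie = unname(tie)
  )
  rpm
}

#' @export
print.trex_regional <- function(x, ...) {
  cat(sprintf(
    "<trex_regional> %d proteins x %d regions%s%s\n",
    length(x$proteins), length(x$regions),
    if (is.null(x$clusters)) "" else
      sprintf(", %d clusters", length(unique(x$clusters))),
    if (is.null(x$specificity)) "" else
      sprintf(", %d multiregional",
              sum(x$specificity$specificity == "multiregional"))
  ))
  invisible(x)
}

# Display bin for a t-score, on the fixed (0, 2, 6, 10) edges.
tscore_bin <- function(x) {
  cut(x, breaks = c(-Inf, T_SCORE_BIN_EDGES, Inf),
      labels = c("<=0", "0-2", "2-6", "6-10", ">=10"), right = TRUE)
}

#' @describeIn assemble_tscore_matrix Long view: one row per protein x
#'   region with `t_score`, `significant`, `absent`, the display `bin` on
#'   the fixed (0, 2, 6, 10) edges, and (when computed) `cluster`,
#'   `specificity`, `primary_region`.
#' @param x A `trex_regional` object.
#' @param ... Unused.
#' @method tidy trex_regional
#' @export
tidy.trex_regional <- function(x, ...) {
  long <- tibble::tibble(
    protein_id = rep(x$proteins, times = length(x$regions)),
    region = rep(x$regions, each = length(x$proteins)),
    t_score = as.vector(x$tscores),
    significant = as.vector(x$significant),
    absent = as.vector(x$absent)
  ) |>
    dplyr::mutate(bin = tscore_bin(.data$t_score))
  if (!is.null(x$clusters)) {
    long$cluster <- unname(x$clusters[long$protein_id])
  }
  if (!is.null(x$specificity)) {
    long <- dplyr::left_join(
      long,
      dplyr::select(x$specificity, "protein_id", "specificity",
                    "primary_region"),
      by = "protein_id"
    )
  }
  long
}
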