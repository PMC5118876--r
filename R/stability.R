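#' Extract major co-expression patterns from one dataset
#'
#' The pattern extractor used by the stability filter: average-linkage
#' hierarchical clustering of features on the distance 1 - Pearson r, with the
#' tree cut at height `1 - corr_cut`. Clusters smaller than
#' `min_cluster_size` are discarded. The extractor is deliberately simple and
#' pluggable — the scientific weight is carried by the resampling/retention
#' protocol of [stability_filter()], which accepts any extractor with this
#' signature.
#'
#' Zero-variance features carry no correlation shape and are excluded before
#' clustering.
#'
#' @param x An [expression_matrix()] (or numeric matrix with dimnames).
#' @param min_cluster_size Minimum members for a cluster to be reported.
#' @param corr_cut Correlation at which the tree is cut; members of a cluster
#'   have average inter-member correlation above this value.
#' @return Named list of character vectors (`P1`, `P2`, ... ordered by
#'   decreasing size, ties by smallest member id); empty list when nothing
#'   survives.
#' @export
extract_patterns <- function(x, min_cluster_size = 10, corr_cut = 0.35) {
  stopifnot(nrow(x) >= min_cluster_size)
  sds <- apply(x, 1L, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 2L) return(stats::setNames(list(), character()))
  v <- x[keep, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(v)))
  hc <- stats::hclust(d, method = "average")
  labs <- stats::cutree(hc, h = 1 - corr_cut)
  sets <- split(rownames(v), labs)
  sets <- lapply(sets, sort)
  sets <- sets[lengths(sets) >= min_cluster_size]
  if (!length(sets)) return(stats::setNames(list(), character()))
  first <- vapply(sets, `[[`, "", 1L)
  sets <- sets[order(-lengths(sets), first)]
  stats::setNames(sets, sprintf("P%d", seq_along(sets)))
}

#' Resampling stability filter for co-expression clusters
#'
#' Implements the subsample-and-retain protocol: a reference clustering is
#' obtained from the full dataset with `extractor`; then, for each of
#' `n_iterations` iterations, `floor(sample_fraction * n_samples)` samples are
#' drawn without replacement, the extractor is re-run, each resampled cluster
#' is matched to the reference cluster of maximal Jaccard overlap (ties to the
#' smaller reference id), and every feature of the resampled cluster has its
#' count for that reference cluster incremented. Features whose best count
#' reaches `retention` are kept, assigned to their best reference cluster.
#' The canonical setting is 1000 iterations at 50% sampling with retention
#' 750; iteration `i` uses a sub-seed derived from (`seed`, `i`).
#'
#' @param x An [expression_matrix()].
#' @param n_iterations Number of resampling iterations.
#' @param sample_fraction Fraction of samples drawn per iteration, in (0, 1].
#' @param retention Minimum selection count for a feature to be retained
#'   (boundary inclusive: a count equal to `retention` is kept).
#' @param seed Integer seed controlling the whole resampling stream.
#' @param min_cluster_size,corr_cut Passed to `extractor`.
#' @param extractor Pattern-extraction function with the signature of
#'   [extract_patterns()].
#' @return A `stable_clusters` object: list with `dataset`, `clusters` (named
#'   list of retained feature sets), `counts` (tibble `feature`, `cluster`,
#'   `count`), `n_iterations`, `params`.
#' @export
stability_filter <- function(x, n_iterations = 1000, sample_fraction = 0.5,
                             retention = 750, seed = 1,
                             min_cluster_size = 10, corr_cut = 0.35,
                             extractor = extract_patterns) {
  stopifnot(retention <= n_iterations,
            sample_fraction > 0, sample_fraction <= 1)
  reference <- extractor(x, min_cluster_size = min_cluster_size,
                         corr_cut = corr_cut)
  if (!length(reference)) {
    stop("reference run produced no clusters; relax corr_cut or ",
         "min_cluster_size", call. = FALSE)
  }
  ref_ids <- names(reference)
  counts <- matrix(0L, nrow(x), length(reference),
                   dimnames = list(rownames(x), ref_ids))
  n_draw <- max(2L, floor(sample_fraction * ncol(x)))
  for (i in seq_len(n_iterations)) {
    set.seed(derive_seed(seed, i))
    cols <- sample(ncol(x), n_draw)
    pats <- extractor(x[, cols, drop = FALSE],
                      min_cluster_size = min_cluster_size,
                      corr_cut = corr_cut)
    for (p in pats) {
      jac <- vapply(reference, jaccard, 0, b = p)
      best <- which(jac == max(jac))[1L]  # ties to the smaller reference id
      if (jac[best] > 0) counts[p, best] <- counts[p, best] + 1L
    }
  }
  best_cl <- max.col(counts, ties.method = "first")
  best_ct <- counts[cbind(seq_len(nrow(counts)), best_cl)]
  keep <- best_ct >= retention
  clusters <- lapply(seq_along(reference), function(ci) {
    sort(rownames(x)[keep & best_cl == ci])
  })
  names(clusters) <- ref_ids
  clusters <- clusters[lengths(clusters) > 0L]
  counts_tbl <- tibble::as_tibble(as.table(counts), .name_repair = "minimal")
  names(counts_tbl) <- c("feature", "cluster", "count")
  structure(list(dataset = dataset_name(x) %||% "dataset",
                 clusters = clusters,
                 counts = counts_tbl,
                 n_iterations = n_iterations,
                 params = list(sample_fraction = sample_fraction,
                               retention = retention, seed = seed,
                               min_cluster_size = min_cluster_size,
                               corr_cut = corr_cut)),
            class = "stable_clusters")
}

#' @export
print.stable_clusters <- function(x, ...) {
  cat(sprintf("<stable_clusters '%s': %d clusters (%s features), %d iterations>\n",
              x$dataset, length(x$clusters),
              sum(lengths(x$clusters)), x$n_iterations))
  invisible(x)
}

#' Flag clusters enriched for immunity-related annotation terms
#'
#' A cluster is flagged when its best (minimum) hypergeometric upper-tail
#' p-value over the immunity-flagged terms falls below `p_cut`.
#'
#' @param clusters A `stable_clusters` object or a named list of feature
#'   sets.
#' @param ann A [feature_annotation()] with nonempty `immune_terms`.
#' @param p_cut Significance cut on the minimum immune-term p-value.
#' @param universe Feature universe for the test; defaults to the annotated
#'   feature domain of `ann`.
#' @return Character vector of flagged cluster ids.
#' @export
flag_immune_clusters <- function(clusters, ann, p_cut = 0.001,
                                 universe = NULL) {
  if (inherits(clusters, "stable_clusters")) clusters <- clusters$clusters
  if (!length(ann$immune_terms)) {
    stop("annotation has no immune-flagged terms", call. = FALSE)
  }
  universe <- universe %||% names(ann$feature_to_gene)
  N <- length(universe)
  flagged <- vapply(clusters, function(cl) {
    cl <- intersect(cl, universe)
    if (!length(cl)) return(FALSE)
    p <- vapply(ann$immune_terms, function(tm) {
      K <- length(intersect(ann$terms[[tm]], universe))
      x <- length(intersect(ann$terms[[tm]], cl))
      hypergeometric_test(N, K, length(cl), x)
    }, 0)
    min(p) < p_cut
  }, logical(1L))
  names(clusters)[flagged]
}
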