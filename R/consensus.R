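#' @useDynLib immunesig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Partition constructor
#'
#' A labeling of items into `k` clusters, as produced by the base clusterers
#' and by the consensus procedure.
#'
#' @param item_ids Character vector of item identifiers.
#' @param labels Integer labels in `1..k`, one per item.
#' @param k Number of clusters (>= 2).
#' @param algorithm Which algorithm produced the labels.
#' @return A `partition` tibble with columns `item` and `label`.
#' @export
partition <- function(item_ids, labels, k, algorithm = c("kmeans", "som")) {
  algorithm <- match.arg(algorithm)
  stopifnot(k >= 2, length(item_ids) == length(labels),
            all(labels >= 1L & labels <= k))
  out <- tibble::tibble(item = as.character(item_ids),
                        label = as.integer(labels))
  attr(out, "k") <- as.integer(k)
  attr(out, "algorithm") <- algorithm
  class(out) <- c("partition", class(out))
  out
}

partition_sets <- function(p) {
  lapply(split(p$item, p$label), sort)
}

# k-means++ seeding followed by stats::kmeans, best of `restarts` by total
# within-cluster sum of squares.
kmeanspp <- function(z, k, restarts = 10) {
  n <- nrow(z)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- integer(k)
    centers[1L] <- sample.int(n, 1L)
    d2 <- rowSums((z - matrix(z[centers[1L], ], n, ncol(z),
                              byrow = TRUE))^2)
    for (j in seq_len(k - 1L)) {
      prob <- d2
      prob[centers[seq_len(j)]] <- 0
      centers[j + 1L] <- if (sum(prob) > 0) {
        sample.int(n, 1L, prob = prob)
      } else {
        setdiff(seq_len(n), centers[seq_len(j)])[1L]
      }
      d2 <- pmin(d2, rowSums((z - matrix(z[centers[j + 1L], ], n, ncol(z),
                                         byrow = TRUE))^2))
    }
    km <- tryCatch(
      stats::kmeans(z, centers = z[centers, , drop = FALSE], iter.max = 100),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed for every restart", call. = FALSE)
  best$cluster
}

#' Cluster standardized feature profiles with a 1 x k self-organizing map
#'
#' Trains a line-topology SOM with exactly `k` nodes online (Gaussian
#' neighborhood and learning rate decaying exponentially over the epochs),
#' then labels each item by its best-matching node. Nodes left empty after
#' training are re-initialized at the item farthest from its matched node and
#' assignment is repeated, so the partition has at most `k` non-empty
#' clusters, relabeled consecutively.
#'
#' @param z Numeric matrix of items x dimensions (standardized profiles).
#' @param k Number of nodes/clusters (>= 2).
#' @param seed Integer seed.
#' @param epochs Training epochs.
#' @return A [partition()] with `algorithm = "som"`.
#' @export
som_cluster <- function(z, k, seed = 1, epochs = 12) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (!all(is.finite(z))) stop("non-finite input to som_cluster",
                               call. = FALSE)
  z <- as.matrix(z)
  n <- nrow(z)
  set.seed(seed)
  init <- z[sample.int(n, k), , drop = FALSE]
  order_mat <- t(vapply(seq_len(epochs), function(e) sample.int(n) - 1L,
                        integer(n)))
  w <- som_train_cpp(z, init, order_mat,
                     alpha0 = 0.5, alpha1 = 0.02,
                     sigma0 = max(k / 2, 1), sigma1 = 0.1)
  labels <- assign_bmu(z, w)
  for (rep in seq_len(k)) {
    empty <- setdiff(seq_len(k), unique(labels))
    if (!length(empty)) break
    d2 <- rowSums((z - w[labels, , drop = FALSE])^2)
    far <- which.max(d2)
    w[empty[1L], ] <- z[far, ]
    labels <- assign_bmu(z, w)
  }
  labels <- match(labels, sort(unique(labels)))
  partition(rownames(z) %||% as.character(seq_len(n)), labels,
            k = max(2L, max(labels)), algorithm = "som")
}

assign_bmu <- function(z, w) {
  d2 <- outer(rowSums(z^2), rep(1, nrow(w))) - 2 * z %*% t(w) +
    outer(rep(1, nrow(z)), rowSums(w^2))
  max.col(-d2, ties.method = "first")
}

#' Consensus clustering of features by resampled k-means or SOM
#'
#' Monti-style consensus clustering over the features of one dataset. Feature
#' profiles are z-scored across samples; for each candidate `k` and each of
#' `n_resamples` iterations, `ceiling(item_fraction * n)` features are
#' subsampled without replacement and clustered. The consensus matrix is the
#' elementwise ratio of co-cluster counts to co-subsample counts (0, with a
#' recorded co-sample count of 0, for pairs never drawn together; diagonal
#' 1). The consensus partition is obtained by average-linkage hierarchical
#' clustering of `1 - consensus` cut into `k` groups, and cluster/item
#' consensus statistics are attached. The canonical protocol is 500 resamples
#' at 80% of features with k up to 10.
#'
#' @param x An [expression_matrix()].
#' @param algorithm `"kmeans"` or `"som"`.
#' @param k_range Integer vector of candidate cluster numbers, within
#'   `[2, n_features - 1]`.
#' @param n_resamples Resampling iterations per `k`.
#' @param item_fraction Fraction of features per subsample, in (0, 1].
#' @param seed Integer seed.
#' @return A named list (class `consensus_set`) of `consensus_result`
#'   objects, one per `k`: list with `dataset`, `algorithm`, `k`, `consensus`,
#'   `co_sample_counts`, `consensus_partition`, `cluster_consensus`,
#'   `item_consensus`.
#' @export
consensus_cluster <- function(x, algorithm = c("kmeans", "som"),
                              k_range = 2:10, n_resamples = 500,
                              item_fraction = 0.8, seed = 1) {
  algorithm <- match.arg(algorithm)
  n <- nrow(x)
  stopifnot(all(k_range >= 2), all(k_range <= n - 1),
            item_fraction > 0, item_fraction <= 1)
  zi <- standardize_rows(unclass(x))  # items (features) in rows, z-scored
  ids <- rownames(x)
  m <- ceiling(item_fraction * n)
  results <- lapply(k_range, function(k) {
    cocluster <- matrix(0, n, n, dimnames = list(ids, ids))
    cosample <- matrix(0L, n, n, dimnames = list(ids, ids))
    r <- 0L
    draws <- 0L
    while (r < n_resamples) {
      draws <- draws + 1L
      set.seed(derive_seed(seed, k * 1000000L + draws))
      idx <- sort(sample.int(n, m))
      if (k > length(idx)) {
        message("resample re-drawn: k exceeds subsample size")
        next
      }
      labels <- switch(algorithm,
        kmeans = kmeanspp(zi[idx, , drop = FALSE], k),
        som = som_cluster(zi[idx, , drop = FALSE], k,
                          seed = derive_seed(seed,
                                             k * 1000000L + draws + 500000L)
        )$label)
      cosample[idx, idx] <- cosample[idx, idx] + 1L
      for (c in unique(labels)) {
        sel <- idx[labels == c]
        cocluster[sel, sel] <- cocluster[sel, sel] + 1
      }
      r <- r + 1L
    }
    consensus <- ifelse(cosample > 0, cocluster / pmax(cosample, 1L), 0)
    diag(consensus) <- 1
    hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
    labels <- stats::cutree(hc, k = k)
    part <- partition(ids, labels, k,
                      algorithm = if (algorithm == "som") "som" else "kmeans")
    structure(list(dataset = dataset_name(x) %||% "dataset",
                   algorithm = algorithm, k = k,
                   consensus = consensus, co_sample_counts = cosample,
                   consensus_partition = part,
                   cluster_consensus = cluster_consensus(consensus, labels),
                   item_consensus = item_consensus(consensus, labels)),
              class = "consensus_result")
  })
  names(results) <- as.character(k_range)
  class(results) <- "consensus_set"
  results
}

# Mean consensus over within-cluster pairs; a singleton cluster has no pairs
# and is assigned consensus 1 by convention.
cluster_consensus <- function(consensus, labels) {
  tibble::tibble(
    cluster = sort(unique(labels)),
    consensus = vapply(sort(unique(labels)), function(c) {
      idx <- which(labels == c)
      if (length(idx) < 2L) return(1)
      cm <- consensus[idx, idx]
      mean(cm[upper.tri(cm)])
    }, 0))
}

# Mean consensus of each item with the members of each cluster (excluding the
# item itself); an item's consensus with its own singleton cluster is 1.
item_consensus <- function(consensus, labels) {
  ids <- rownames(consensus)
  grid <- expand.grid(item = seq_along(ids), cluster = sort(unique(labels)),
                      KEEP.OUT.ATTRS = FALSE)
  grid$value <- mapply(function(i, c) {
    idx <- setdiff(which(labels == c), i)
    if (!length(idx)) return(1)
    mean(consensus[i, idx])
  }, grid$item, grid$cluster)
  tibble::tibble(item = ids[grid$item], cluster = grid$cluster,
                 consensus = grid$value)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result '%s' %s k=%d: mean cluster consensus %.3f>\n",
              x$dataset, x$algorithm, x$k, mean(x$cluster_consensus$consensus)))
  invisible(x)
}

#' Summarize a consensus-clustering run across candidate k
#'
#' @param x A `consensus_set` from [consensus_cluster()].
#' @param ... Unused.
#' @return Tibble with one row per `k`: CDF area `A`, relative area increase
#'   `delta`, mean and minimum cluster consensus.
#' @export
tidy.consensus_set <- function(x, ...) {
  ks <- as.integer(names(x))
  area <- vapply(x, function(res) {
    u <- res$consensus[upper.tri(res$consensus)]
    1 - mean(u)  # area under the ECDF of entries in [0,1]
  }, 0)
  delta <- c(area[1L],
             if (length(area) > 1L) diff(area) / area[-length(area)])
  tibble::tibble(
    k = ks, area = area, delta = delta,
    mean_cluster_consensus = vapply(x, function(res) {
      mean(res$cluster_consensus$consensus)
    }, 0),
    min_cluster_consensus = vapply(x, function(res) {
      min(res$cluster_consensus$consensus)
    }, 0))
}

#' Select the number of clusters from consensus summary statistics
#'
#' Applies the consensus-CDF area criterion: the chosen `k` maximizes the
#' relative increase in area under the empirical CDF of consensus entries
#' (for the smallest candidate the area itself), restricted to candidates
#' whose mean cluster consensus reaches `consensus_floor`. Ties break to the
#' smaller `k`; when no candidate reaches the floor the restriction is
#' dropped with a warning. The selection statistics are meant to be surfaced
#' ([tidy.consensus_set()]) so a user can override per dataset.
#'
#' @param results A `consensus_set` from [consensus_cluster()].
#' @param consensus_floor Minimum mean cluster consensus for eligibility.
#' @return Integer: the selected `k`.
#' @export
select_k <- function(results, consensus_floor = 0.8) {
  s <- tidy.consensus_set(results)
  if (nrow(s) == 1L) return(s$k)
  elig <- s$mean_cluster_consensus >= consensus_floor
  if (!any(elig)) {
    warning("no candidate k reaches the cluster-consensus floor; ",
            "selecting on the area criterion alone")
    elig <- rep(TRUE, nrow(s))
  }
  cand <- s[elig, ]
  cand$k[order(-cand$delta, cand$k)][1L]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (Hubert–Arabie form, computed from the contingency table). Returns 1 for
#' identical partitions and has expectation 0 under random label
#' permutations.
#'
#' @param p,q [partition()] tibbles (matched by item id), or plain label
#'   vectors of equal length.
#' @return The adjusted Rand index (a real number, at most 1).
#' @export
adjusted_rand <- function(p, q) {
  if (inherits(p, "partition") && inherits(q, "partition")) {
    if (!setequal(p$item, q$item)) {
      stop("partitions are over different item sets", call. = FALSE)
    }
    q <- q[match(p$item, q$item), ]
    a <- p$label; b <- q$label
  } else {
    if (length(p) != length(q)) {
      stop("partitions are over different item sets", call. = FALSE)
    }
    a <- as.integer(factor(p)); b <- as.integer(factor(q))
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
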