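separated <- function(k = 3, size = 10, n_samples = 25, seed = 1) {
  toy_modular(n_mod = k, size = size, n_samples = n_samples, noise = 0.05,
              seed = seed)
}

test_that("consensus matrices satisfy their structural invariants", {
  x <- toy_modular(n_mod = 2, size = 8, noise = 0.8, seed = 1)
  for (alg in c("kmeans", "som")) {
    res <- consensus_cluster(x, algorithm = alg, k_range = 2:3,
                             n_resamples = 15, seed = 3)
    for (r in res) {
      expect_true(isSymmetric(r$consensus))
      expect_equal(unname(diag(r$consensus)), rep(1, nrow(x)))
      expect_true(all(r$consensus >= 0 & r$consensus <= 1))
      expect_true(isSymmetric(r$co_sample_counts))
    }
  }
})

test_that("full-item-fraction consensus equals the co-membership indicator", {
  x <- separated(k = 3, seed = 5)
  res <- consensus_cluster(x, algorithm = "kmeans", k_range = 3,
                           n_resamples = 8, item_fraction = 1, seed = 7)
  cons <- res[["3"]]$consensus
  expect_true(all(cons %in% c(0, 1)))
  labels <- res[["3"]]$consensus_partition$label
  indicator <- outer(labels, labels, "==") * 1
  dimnames(indicator) <- dimnames(cons)
  expect_equal(cons, indicator)
})

test_that("well-separated modules give sharp consensus, noise does not", {
  x <- separated(k = 3, seed = 2)
  res <- consensus_cluster(x, algorithm = "kmeans", k_range = 3,
                           n_resamples = 40, seed = 11)[["3"]]
  labels <- res$consensus_partition$label
  within <- outer(labels, labels, "==")
  diag(within) <- NA
  expect_true(all(res$consensus[which(within)] >= 0.95))
  expect_true(all(res$consensus[which(!within)] <= 0.05))

  set.seed(13)
  noise <- expression_matrix(
    matrix(rnorm(30 * 25), 30, 25,
           dimnames = list(sprintf("n%02d", 1:30), sprintf("s%02d", 1:25))),
    "noise")
  nres <- consensus_cluster(noise, algorithm = "kmeans", k_range = 3,
                            n_resamples = 40, seed = 11)[["3"]]
  expect_lt(mean(nres$cluster_consensus$consensus),
            mean(res$cluster_consensus$consensus))
  u <- nres$consensus[upper.tri(nres$consensus)]
  expect_gt(mean(u > 0.05 & u < 0.95), 0.3)  # entries pile up in the interior
})

test_that("pairs never co-sampled have consensus 0 with count 0 recorded", {
  x <- separated(k = 2, size = 12, seed = 3)
  res <- consensus_cluster(x, algorithm = "kmeans", k_range = 2,
                           n_resamples = 2, item_fraction = 0.3,
                           seed = 1)[["2"]]
  off <- res$co_sample_counts[upper.tri(res$co_sample_counts)] == 0
  expect_gt(sum(off), 0)
  expect_true(all(res$consensus[upper.tri(res$consensus)][off] == 0))
})

test_that("the consensus-CDF criterion selects the planted cluster number", {
  x <- separated(k = 3, seed = 4)
  for (alg in c("kmeans", "som")) {
    res <- consensus_cluster(x, algorithm = alg, k_range = 2:5,
                             n_resamples = 40, seed = 21)
    expect_equal(select_k(res), 3L)
  }
})

test_that("k selection tie-breaks to the smaller k and handles one candidate", {
  x <- separated(k = 2, size = 10, seed = 6)
  res <- consensus_cluster(x, algorithm = "kmeans", k_range = 3,
                           n_resamples = 10, seed = 2)
  expect_equal(select_k(res), 3L)
  # identical summary statistics for two k: the smaller k wins
  twin <- res[c("3", "3")]
  names(twin) <- c("4", "5")
  twin[["4"]]$k <- 4L; twin[["5"]]$k <- 5L
  class(twin) <- "consensus_set"
  s <- tidy(twin)
  expect_equal(unname(s$delta[2]), 0)
  expect_equal(select_k(twin), 4L)
})

test_that("ARI matches closed forms and the pair-count brute force", {
  p <- partition(letters[1:10], rep(1:2, each = 5), 2)
  expect_equal(adjusted_rand(p, p), 1)
  ones <- rep(1L, 10)
  singl <- 1:10
  expect_equal(adjusted_rand(ones, singl), 0)
  expect_error(adjusted_rand(p, partition(letters[2:11],
                                          rep(1:2, each = 5), 2)),
               "item sets")

  parts5 <- all_partitions(5)
  idx <- expand.grid(i = seq_along(parts5), j = seq_along(parts5))
  got <- mapply(function(i, j) adjusted_rand(parts5[[i]], parts5[[j]]),
                idx$i, idx$j)
  want <- mapply(function(i, j) ari_paircounts(parts5[[i]], parts5[[j]]),
                 idx$i, idx$j)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("ARI agrees with an independent library implementation", {
  skip_if_not_installed("mclust")
  set.seed(2)
  for (i in 1:20) {
    a <- sample(1:4, 30, TRUE)
    b <- sample(1:3, 30, TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI has mean about zero under random label permutation", {
  set.seed(3)
  a <- rep(1:3, each = 20)
  vals <- replicate(1000, adjusted_rand(a, sample(a)))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("the SOM partitioner matches k-means on separated data", {
  x <- separated(k = 3, seed = 8)
  z <- t(apply(unclass(x), 1, function(r) (r - mean(r)) / sd(r)))
  som <- som_cluster(z, k = 3, seed = 4)
  km <- partition(rownames(z), kmeans(z, 3, nstart = 10)$cluster, 3)
  expect_equal(adjusted_rand(som, km), 1)
  expect_identical(som_cluster(z, k = 3, seed = 4)$label, som$label)
  expect_error(som_cluster(z, k = 1), "k must be >= 2")
  expect_error(som_cluster(z * NA, k = 2), "non-finite")
})
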