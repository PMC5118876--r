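# Shared fixtures and independent brute-force oracles.

# Small factor-model matrix with `n_mod` planted modules of `size` genes plus
# `n_noise` pure-noise genes; returns an expr_matrix. Built directly (not via
# the package generator) so it can serve as an independent fixture.
toy_modular <- function(n_mod = 2, size = 12, n_samples = 40, noise = 0.3,
                        n_noise = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (m in seq_len(n_mod)) {
    f <- rnorm(n_samples)
    block <- sapply(seq_len(n_samples), function(j) f[j]) # latent factor
    vals <- matrix(rep(f, each = size), size, n_samples) +
      matrix(rnorm(size * n_samples, sd = noise), size)
    rownames(vals) <- sprintf("M%dg%02d", m, seq_len(size))
    rows[[m]] <- vals
  }
  if (n_noise > 0) {
    nz <- matrix(rnorm(n_noise * n_samples), n_noise, n_samples,
                 dimnames = list(sprintf("N%02d", seq_len(n_noise)), NULL))
    rows[[length(rows) + 1L]] <- nz
  }
  vals <- do.call(rbind, rows)
  colnames(vals) <- sprintf("s%02d", seq_len(n_samples))
  expression_matrix(vals + 8, "toy")
}

# All set partitions of n items (restricted growth strings).
all_partitions <- function(n) {
  grow <- function(prefix) {
    if (length(prefix) == n) return(list(prefix))
    mx <- if (length(prefix)) max(prefix) else 0L
    out <- list()
    for (v in seq_len(mx + 1L)) {
      out <- c(out, grow(c(prefix, v)))
    }
    out
  }
  grow(integer())
}

# ARI from explicit pair counts (agreements/disagreements over all item
# pairs) — independent of the contingency-table implementation.
ari_paircounts <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  num / den
}

# Hypergeometric upper tail by direct combinatorial summation.
hyper_enum <- function(N, K, n, x) {
  js <- x:min(K, n)
  js <- js[n - js <= N - K]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# All maximal cliques of an adjacency matrix by exhaustive subset search
# (feasible for <= 6 nodes).
bf_max_cliques <- function(adj) {
  ids <- rownames(adj)
  n <- length(ids)
  subsets <- unlist(lapply(2:n, function(k) {
    utils::combn(n, k, simplify = FALSE)
  }), recursive = FALSE)
  is_clique <- vapply(subsets, function(s) {
    all(adj[s, s][upper.tri(diag(length(s)))])
  }, logical(1))
  cl <- subsets[is_clique]
  maximal <- cl[vapply(seq_along(cl), function(i) {
    !any(vapply(cl, function(other) {
      length(other) > length(cl[[i]]) && all(cl[[i]] %in% other)
    }, logical(1)))
  }, logical(1))]
  lapply(maximal, function(s) sort(ids[s]))
}

# Toy annotation over an explicit feature universe: every feature is its own
# symbol; one immune term per supplied set plus optional decoys.
toy_annotation <- function(universe, immune_sets = list(),
                           decoys = list()) {
  terms <- c(immune_sets, decoys)
  if (is.null(names(terms)) || any(names(terms) == "")) {
    names(terms) <- sprintf("T%02d", seq_along(terms))
  }
  feature_annotation(stats::setNames(universe, universe), terms = terms,
                     immune_terms = utils::head(names(terms),
                                                length(immune_sets)))
}
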