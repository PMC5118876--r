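toy_panel <- function(group_means, n_per_group = 4, noise_sd = 0, seed = 1,
                      features = names(group_means[[1]])) {
  set.seed(seed)
  groups <- names(group_means)
  samples <- unlist(lapply(groups, function(g) {
    sprintf("%s_r%d", g, seq_len(n_per_group))
  }))
  s2g <- stats::setNames(rep(groups, each = n_per_group), samples)
  vals <- sapply(samples, function(s) {
    g <- s2g[[s]]
    group_means[[g]] + rnorm(length(features), sd = noise_sd)
  })
  vals <- matrix(vals, nrow = length(features),
                 dimnames = list(features, samples))
  if (nrow(vals) < 2L) {  # container needs >= 2 features
    vals <- rbind(vals, zz_filler = rnorm(ncol(vals)))
  }
  reference_panel(expression_matrix(vals, "panel"), s2g, groups = groups)
}

test_that("equal group means give zero coefficients and p = 1", {
  mus <- list(A = c(f1 = 5, f2 = 3), B = c(f1 = 5, f2 = 3),
              C = c(f1 = 5, f2 = 3))
  panel <- toy_panel(mus, noise_sd = 0.4, seed = 2)
  # exact equality case: zero noise, degenerate contract
  flat <- toy_panel(mus, noise_sd = 0)
  pc <- pairwise_contrasts(flat, "f1")
  expect_true(all(pc$coefficient == 0))
  expect_true(all(pc$p_value == 1))
  prof <- enrichment_scores(flat, c("f1", "f2"))
  expect_true(all(prof$scores == 0))
})

test_that("contrasts match a least-squares group-means oracle", {
  mus <- list(A = c(f1 = 2), B = c(f1 = 5), C = c(f1 = 3.5))
  panel <- toy_panel(mus, n_per_group = 2, noise_sd = 1, seed = 3)
  pc <- pairwise_contrasts(panel, "f1")
  y <- unclass(panel$expression)["f1", ]
  g <- factor(panel$sample_to_group, levels = panel$groups)
  for (r in seq_len(nrow(pc))) {
    rel <- stats::relevel(g, ref = pc$other[r])
    fit <- stats::lm(y ~ rel)
    co <- summary(fit)$coefficients[paste0("rel", pc$group[r]), ]
    expect_equal(pc$coefficient[r], unname(co["Estimate"]),
                 tolerance = 1e-10)
    expect_equal(pc$p_value[r], unname(co["Pr(>|t|)"]), tolerance = 1e-10)
  }
  # antisymmetry is exact
  key <- paste(pc$other, pc$group)
  flip <- pc$coefficient[match(paste(pc$group, pc$other), key)]
  expect_equal(pc$coefficient, -flip)
})

test_that("planted markers score highest in their own group", {
  pan <- simulate_reference_panel(group_sizes = c(A = 5, B = 5, C = 5,
                                                  D = 5),
                                  markers_per_group = 6, effect = 4,
                                  noise_sd = 1, seed = 9)
  prof <- enrichment_scores(pan$panel, rownames(pan$panel$expression))
  for (g in names(pan$group_markers)) {
    top <- colnames(prof$scores)[max.col(prof$scores[
      pan$group_markers[[g]], , drop = FALSE])]
    expect_true(all(top == g))
  }
})

test_that("scores of a saturated-effect feature sum to zero across groups", {
  mus <- list(A = c(f1 = 0), B = c(f1 = 10), C = c(f1 = 25),
              D = c(f1 = 40))
  panel <- toy_panel(mus, n_per_group = 4, noise_sd = 0.2, seed = 5)
  prof <- enrichment_scores(panel, "f1")
  # every pair is significant at these effect sizes
  pc <- pairwise_contrasts(panel, "f1")
  expect_true(all(pc$p_value <= 0.05 / choose(4, 2)))
  expect_equal(sum(prof$scores), 0, tolerance = 1e-9)
})

test_that("raising alpha never removes contributing contrasts", {
  mus <- list(A = c(f1 = 1), B = c(f1 = 2.2), C = c(f1 = 3))
  panel <- toy_panel(mus, n_per_group = 3, noise_sd = 1, seed = 6)
  pc <- pairwise_contrasts(panel, "f1")
  thr <- function(a) sum(pc$p_value <= a / choose(3, 2))
  alphas <- c(0.01, 0.05, 0.2, 0.8)
  expect_true(all(diff(vapply(alphas, thr, 0)) >= 0))
})

test_that("signature profiles average member scores", {
  pan <- simulate_reference_panel(group_sizes = c(A = 4, B = 4, C = 4),
                                  markers_per_group = 5, effect = 3,
                                  seed = 11)
  feats <- rownames(pan$panel$expression)
  prof <- enrichment_scores(pan$panel, feats)
  sigs <- list(SigA = pan$group_markers$A, single = feats[1])
  sp <- profile_signatures(prof, sigs)
  expect_equal(sp["single", ], prof$scores[feats[1], ])
  expect_equal(sp["SigA", ],
               colMeans(prof$scores[pan$group_markers$A, ]))
  expect_equal(unname(which.max(sp["SigA", ])),
               which(colnames(sp) == "A"))
  # invariant to member order
  sp2 <- profile_signatures(prof, list(SigA = rev(sigs$SigA)))
  expect_equal(sp2["SigA", ], sp["SigA", ])
})
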