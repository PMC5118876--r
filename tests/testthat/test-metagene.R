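test_that("metagene values follow the two-step averaging contract", {
  vals <- rbind(p1 = c(2, 1), p2 = c(4, 3), q = c(6, 5))
  colnames(vals) <- c("s1", "s2")
  x <- expression_matrix(vals, "toy")
  ann <- feature_annotation(c(p1 = "G", p2 = "G", q = NA))
  m <- compute_metagenes(x, list(sig = c("p1", "p2", "q")), ann)
  expect_equal(unname(unclass(m)["sig", ]), c(mean(c(mean(c(2, 4)), 6)),
                                              mean(c(mean(c(1, 3)), 5))))
  expect_equal(unclass(m)["sig", "s1"], 4.5)
  one <- compute_metagenes(x, list(solo = "q"), ann)
  expect_equal(unname(unclass(one)["solo", ]), unname(vals["q", ]))
})

test_that("planted-module metagenes track the latent factor", {
  sim <- simulate_datasets(n_datasets = 2, n_samples = 80, n_conserved = 2,
                           n_private = 1, module_size = 15,
                           n_background = 30, noise_sd = 0.6, seed = 3)
  ann <- simulate_annotation(sim$truth, n_decoy_terms = 5, seed = 3)
  x <- sim$datasets[[1]]
  mods <- sim$truth$conserved_modules
  m <- compute_metagenes(x, mods, ann)
  for (nm in names(mods)) {
    # the module mean profile is the best available factor surrogate
    factor_est <- colMeans(unclass(x)[mods[[nm]], ])
    expect_gte(abs(cor(unclass(m)[nm, ], factor_est)), 0.9)
  }
})

test_that("metagene dendrograms are deterministic and reject constants", {
  set.seed(4)
  base <- rnorm(30)
  m <- rbind(a = base + rnorm(30, sd = 0.1), b = base + rnorm(30, sd = 0.1),
             c = rnorm(30), d = rnorm(30))
  colnames(m) <- sprintf("s%02d", 1:30)
  tree <- metagene_dendrogram(m)
  # correlated pair merges first, at low height
  merge1 <- sort(tree$labels[-tree$merge[1, ]])
  expect_equal(merge1, c("a", "b"))
  expect_lt(tree$height[1], 0.5)
  # identical metagenes merge at height 0
  dup <- rbind(a = base, b = base, c = rnorm(30))
  colnames(dup) <- colnames(m)
  tdup <- metagene_dendrogram(dup)
  expect_equal(min(tdup$height), 0, tolerance = 1e-12)
  # order invariance
  t2 <- metagene_dendrogram(m[c(3, 1, 4, 2), ])
  expect_equal(stats::cophenetic(tree), stats::cophenetic(t2))
  bad <- rbind(a = rep(1, 30), b = rnorm(30))
  colnames(bad) <- colnames(m)
  expect_error(metagene_dendrogram(bad), "a")
})

test_that("Cox fit matches a grid-search partial-likelihood oracle", {
  # four observations, no ties
  clin <- clinical_table(tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    time = c(1, 2, 3, 4), event = c(1, 1, 0, 1)))
  z <- c(s1 = 0.5, s2 = -1, s3 = 0.2, s4 = 1.3)
  row <- cox_univariate(z, clin)
  # oracle: maximize the exact partial likelihood over a fine beta grid
  logpl <- function(b) {
    risk <- exp(b * z)
    events <- c("s1", "s2", "s4")
    sum(vapply(events, function(s) {
      at_risk <- names(z)[clin$time[match(names(z), clin$sample_id)] >=
                            clin$time[clin$sample_id == s]]
      b * z[[s]] - log(sum(risk[at_risk]))
    }, 0))
  }
  grid <- seq(-5, 5, by = 1e-4)
  beta_star <- grid[which.max(vapply(grid, logpl, 0))]
  expect_equal(row$beta, beta_star, tolerance = 1e-3)
  expect_equal(row$hazard_ratio, exp(row$beta))
  expect_true(row$ci_low <= row$hazard_ratio &
                row$hazard_ratio <= row$ci_high)
})

test_that("Efron and Breslow agree exactly on tie-free data", {
  set.seed(5)
  n <- 60
  z <- stats::setNames(rnorm(n), sprintf("s%02d", 1:n))
  clin <- simulate_survival(matrix(z, 1, dimnames = list("m", names(z))),
                            betas = c(m = -0.4), baseline_rate = 0.2,
                            censor_rate = 0.05, seed = 6)
  expect_equal(anyDuplicated(clin$time[clin$event == 1]), 0L)
  efron <- cox_univariate(z, clin, ties = "efron")
  breslow <- cox_univariate(z, clin, ties = "breslow")
  expect_equal(efron$beta, breslow$beta, tolerance = 1e-8)
})

test_that("degenerate survival inputs raise errors", {
  clin <- clinical_table(tibble::tibble(sample_id = c("s1", "s2"),
                                        time = c(1, 2), event = c(0, 0)))
  expect_error(cox_univariate(c(s1 = 1, s2 = 2), clin), "events")
  clin2 <- clinical_table(tibble::tibble(sample_id = c("a", "b"),
                                         time = c(1, 2), event = c(1, 0)))
  expect_error(cox_univariate(c(s1 = 1, s2 = 2), clin2), "overlapping")
})

test_that("tertile binning splits nine distinct values 3/3/3", {
  b <- immunesig:::tertile_bins(c(5, 1, 9, 2, 8, 3, 7, 4, 6))
  expect_equal(as.vector(table(b)), c(3L, 3L, 3L))
})

test_that("the all-samples stratum reproduces the unstratified fit", {
  set.seed(7)
  n <- 80
  mg <- matrix(rnorm(2 * n), 2, n,
               dimnames = list(c("Sig01", "Sig02"), sprintf("s%03d", 1:n)))
  clin <- simulate_survival(mg, betas = c(Sig01 = -0.6, Sig02 = 0),
                            baseline_rate = 0.2, censor_rate = 0.05,
                            seed = 8)
  clin$grade <- rep(c("lo", "hi"), length.out = n)
  m <- structure(mg, class = "metagene_table")
  rep_all <- stratified_survival(m, clin, strata_spec = "grade")
  base <- cox_univariate(mg["Sig01", ], clin, metagene = "Sig01")
  row <- dplyr::filter(rep_all, metagene == "Sig01", stratum == "all")
  expect_equal(row$beta, base$beta, tolerance = 1e-12)
  expect_equal(row$p_value, base$p_value, tolerance = 1e-12)
  expect_setequal(unique(rep_all$stratum), c("all", "grade=hi", "grade=lo"))
  g <- glance(rep_all)
  expect_equal(g$n_metagenes, 2L)
})

test_that("a planted tertile-specific effect is found in its tertile", {
  set.seed(9)
  n <- 900
  prolif <- rnorm(n)
  mg <- rnorm(n)
  names(mg) <- sprintf("s%04d", 1:n)
  bins <- immunesig:::tertile_bins(prolif)
  lp <- ifelse(bins == "high", -0.9 * mg, 0)
  t_event <- rexp(n, rate = 0.2 * exp(lp))
  t_cens <- rexp(n, rate = 0.04)
  clin <- clinical_table(tibble::tibble(
    sample_id = names(mg), time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens), P = prolif))
  m <- structure(matrix(mg, 1, dimnames = list("Sig01", names(mg))),
                 class = "metagene_table")
  rep <- stratified_survival(m, clin, strata_spec = list(P = "tertiles"))
  p_high <- dplyr::filter(rep, stratum == "P=high")$p_value
  p_low <- dplyr::filter(rep, stratum == "P=low")$p_value
  expect_lt(p_high, 0.001)
  expect_gt(p_low, 0.05)
  expect_equal(dplyr::filter(rep, stratum == "P=high")$stars, "***")
})
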