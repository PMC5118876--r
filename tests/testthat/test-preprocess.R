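# Build a probe-level matrix with controlled pairwise correlation structure.
probe_matrix <- function(rows, n = 30, seed = 1) {
  set.seed(seed)
  vals <- do.call(rbind, rows)
  colnames(vals) <- sprintf("s%02d", seq_len(ncol(vals)))
  expression_matrix(vals, "probes")
}

probe_ann <- function(probes, genes) {
  feature_annotation(stats::setNames(genes, probes))
}

test_that("perfectly correlated probes collapse to their mean row", {
  set.seed(1)
  base <- rnorm(30)
  vals <- rbind(p1 = base, p2 = base + 2, p3 = rnorm(30))
  x <- probe_matrix(list(vals))
  ann <- probe_ann(c("p1", "p2", "p3"), c("G1", "G1", "G2"))
  out <- collapse_probes(x, ann)
  expect_equal(nrow(out$matrix), 2L)
  expect_equal(unname(unclass(out$matrix)["G1", ]),
               unname(colMeans(vals[c("p1", "p2"), ])))
})

test_that("anti-correlated probes of one gene stay separate", {
  set.seed(2)
  base <- rnorm(30)
  vals <- rbind(p1 = base, p2 = -base + rnorm(30, sd = 0.3))
  expect_lt(cor(vals[1, ], vals[2, ]), -0.8)
  x <- probe_matrix(list(vals))
  out <- collapse_probes(x, probe_ann(c("p1", "p2"), c("G1", "G1")))
  expect_setequal(rownames(out$matrix), c("p1", "p2"))
})

test_that("grouping matches the exhaustive maximal-clique oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    k <- sample(3:6, 1)
    f <- rnorm(40)
    vals <- t(sapply(seq_len(k), function(i) {
      w <- runif(1)
      w * f + rnorm(40, sd = runif(1, 0.2, 2))
    }))
    rownames(vals) <- sprintf("p%d", seq_len(k))
    # extra unannotated probe keeps the output matrix at >= 2 rows even
    # when every gated probe merges into one group
    extra <- matrix(rnorm(40), 1, dimnames = list("zz_extra", NULL))
    x <- probe_matrix(list(rbind(vals, extra)))
    ann <- probe_ann(c(rownames(vals), "zz_extra"), c(rep("G1", k), NA))
    out <- collapse_probes(x, ann)

    # oracle: greedy largest-maximal-clique extraction on the r>0.4 graph
    remaining <- sort(rownames(vals))
    expected <- list()
    repeat {
      if (length(remaining) < 2) break
      adj <- cor(t(vals[remaining, , drop = FALSE])) > 0.4
      diag(adj) <- FALSE
      if (!any(adj)) break
      cl <- bf_max_cliques(adj)
      keys <- vapply(cl, paste, "", collapse = "\r")
      pick <- cl[[order(-lengths(cl), keys)[1]]]
      expected[[length(expected) + 1]] <- pick
      remaining <- setdiff(remaining, pick)
    }
    got <- out$groups$members[out$groups$n_members > 1]
    expect_identical(got[order(vapply(got, `[[`, "", 1))],
                     expected[order(vapply(expected, `[[`, "", 1))],
                     info = sprintf("seed %d", seed))
  }
})

test_that("zero-variance probes bypass gating and pass through", {
  set.seed(3)
  vals <- rbind(p1 = rnorm(20), p2 = rep(5, 20), p3 = rnorm(20))
  x <- probe_matrix(list(vals))
  ann <- probe_ann(c("p1", "p2", "p3"), c("G1", "G1", "G2"))
  expect_message(out <- collapse_probes(x, ann), "zero-variance")
  expect_true(all(c("p1", "p2") %in% rownames(out$matrix)))
})

test_that("collapsing never grows the matrix and ignores row order", {
  set.seed(4)
  base <- rnorm(25)
  vals <- rbind(a = base + rnorm(25, sd = 0.1),
                b = base + rnorm(25, sd = 0.1),
                c = rnorm(25), d = rnorm(25))
  ann <- probe_ann(c("a", "b", "c", "d"), c("G1", "G1", "G2", NA))
  x1 <- probe_matrix(list(vals))
  x2 <- probe_matrix(list(vals[c(3, 1, 4, 2), ]))
  o1 <- collapse_probes(x1, ann)
  o2 <- collapse_probes(x2, ann)
  expect_lte(nrow(o1$matrix), nrow(x1))
  expect_identical(unclass(o1$matrix)[, ], unclass(o2$matrix)[, ])
})

test_that("take_union matches sort-unique and expands collapsed probes", {
  expect_equal(take_union(list(list(c("a", "b")), list(c("b", "c")))),
               c("a", "b", "c"))
  sets <- lapply(1:5, function(i) {
    list(sprintf("f%02d", (i - 1) * 10 + 1:10))
  })
  expect_length(take_union(sets), 50L)
  set.seed(5)
  rand <- lapply(1:5, function(i) list(sample(letters, 8)))
  expect_equal(take_union(rand),
               sort(unique(unlist(rand))))
  # collapsed-id expansion back to probe space
  groups <- tibble::tibble(collapsed_id = "G1", gene = "G1",
                           members = list(c("p1", "p2")), n_members = 2L)
  expect_equal(take_union(list(list(c("G1", "q9"))), list(groups)),
               c("p1", "p2", "q9"))
})
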