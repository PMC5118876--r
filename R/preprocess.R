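#' Collapse correlated probe sets to gene-level rows
#'
#' Probes annotated with the same gene symbol are merged when they agree:
#' within a gene, probes are grouped into maximal cliques of the probe-probe
#' graph whose edges are Pearson r greater than `r_threshold` (computed across
#' all samples of this dataset), so every averaged pair individually satisfies
#' the correlation gate. Cliques are merged greedily, largest first (ties
#' broken lexicographically on the sorted member ids); each merged group is
#' replaced by the arithmetic mean of its member rows. Probes failing the
#' gate, lacking a symbol, or with zero variance pass through unchanged.
#'
#' @param x An [expression_matrix()].
#' @param ann A [feature_annotation()] supplying probe -> gene symbols.
#' @param r_threshold Pearson correlation gate, in (-1, 1). Default 0.4.
#' @return List with `matrix` (the collapsed [expression_matrix()], rows
#'   sorted by id) and `groups` (tibble: `collapsed_id`, `gene`, `members`
#'   list-column, `n_members`) covering every output row.
#' @export
collapse_probes <- function(x, ann, r_threshold = 0.4) {
  stopifnot(r_threshold > -1, r_threshold < 1)
  f2g <- ann$feature_to_gene
  probes <- rownames(x)
  gene <- f2g[probes]
  sds <- apply(x, 1L, stats::sd)
  gateable <- !is.na(gene) & sds > 0
  if (any(!is.na(gene) & sds == 0)) {
    message("zero-variance probe(s) excluded from correlation gating: ",
            paste(probes[!is.na(gene) & sds == 0], collapse = ", "))
  }

  groups <- list()
  taken <- character()
  for (g in unique(gene[gateable])) {
    members <- probes[gateable & !is.na(gene) & gene == g]
    remaining <- sort(members)
    while (length(remaining) >= 2L) {
      cl <- best_clique(x[remaining, , drop = FALSE], r_threshold)
      if (is.null(cl)) break
      groups[[length(groups) + 1L]] <- list(gene = g, members = cl)
      remaining <- setdiff(remaining, cl)
    }
    for (p in remaining) {  # singletons pass through
      groups[[length(groups) + 1L]] <- list(gene = g, members = p)
    }
  }
  # passthrough: no symbol or zero variance
  for (p in probes[!gateable]) {
    groups[[length(groups) + 1L]] <-
      list(gene = if (is.na(gene[[p]])) NA_character_ else gene[[p]],
           members = p)
  }

  ids <- character(length(groups))
  counts <- list()
  for (i in seq_along(groups)) {
    gr <- groups[[i]]
    if (length(gr$members) == 1L) {
      ids[i] <- gr$members
    } else {
      base <- gr$gene
      k <- (counts[[base]] %||% 0L) + 1L
      counts[[base]] <- k
      cand <- if (k == 1L) base else sprintf("%s.%d", base, k)
      while (cand %in% probes || cand %in% ids) cand <- paste0(cand, "_avg")
      ids[i] <- cand
    }
  }
  rows <- t(vapply(groups, function(gr) {
    colMeans(x[gr$members, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(rows) <- ids
  ord <- order(ids)
  out <- expression_matrix(rows[ord, , drop = FALSE], dataset_name(x))
  tab <- tibble::tibble(
    collapsed_id = ids,
    gene = vapply(groups, function(gr) gr$gene %||% NA_character_, ""),
    members = lapply(groups, function(gr) sort(gr$members)),
    n_members = lengths(lapply(groups, `[[`, "members")))[ord, ]
  list(matrix = out, groups = tab)
}

# Largest maximal clique (ties lexicographic on sorted members) of the graph
# with edges r > threshold among the given probe rows.
best_clique <- function(sub, r_threshold) {
  r <- suppressWarnings(stats::cor(t(sub)))
  adj <- r > r_threshold
  diag(adj) <- FALSE
  if (!any(adj)) return(NULL)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(g, min = 2L)
  if (!length(cl)) return(NULL)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  keys <- vapply(cl, paste, "", collapse = "\r")
  cl[[order(-lengths(cl), keys)[1L]]]
}

#' Union of stable-cluster memberships across datasets
#'
#' Takes the per-dataset collections of (typically immune-flagged) stable
#' clusters and returns the exact set union of their members, in deterministic
#' sorted order. When probe collapsing was applied upstream, pass the
#' per-dataset `groups` tables from [collapse_probes()] to expand collapsed
#' ids back to the original probe ids before the union.
#'
#' @param cluster_sets List over datasets; each element is a list of character
#'   vectors (cluster member ids) or a `stable_clusters` object.
#' @param probe_groups Optional list over datasets of [collapse_probes()]
#'   `groups` tables used to expand collapsed ids.
#' @return Sorted character vector of feature ids.
#' @export
take_union <- function(cluster_sets, probe_groups = NULL) {
  members <- unlist(lapply(seq_along(cluster_sets), function(i) {
    cs <- cluster_sets[[i]]
    if (inherits(cs, "stable_clusters")) cs <- cs$clusters
    ids <- unlist(cs, use.names = FALSE)
    if (!is.null(probe_groups)) {
      tab <- probe_groups[[i]]
      hit <- match(ids, tab$collapsed_id)
      expanded <- unlist(tab$members[hit[!is.na(hit)]], use.names = FALSE)
      ids <- c(ids[is.na(hit)], expanded)
    }
    ids
  }), use.names = FALSE)
  sort(unique(members))
}
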