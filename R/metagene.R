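#' Collapse signatures to per-sample metagenes
#'
#' Two-step averaging so that no gene is over-represented: within a
#' signature, (1) probe sets sharing a gene symbol are averaged per sample;
#' (2) those per-gene values together with the remaining symbol-less probe
#' values are averaged per sample to give the metagene value. Signature
#' members absent from the matrix are dropped with a message; a signature
#' with no present members yields a missing row.
#'
#' @param x An [expression_matrix()].
#' @param signatures A `signature_set` or named list of member-id vectors.
#' @param ann A [feature_annotation()] supplying probe -> gene symbols.
#' @return A `metagene_table`: numeric matrix signatures x samples with a
#'   `dataset` attribute.
#' @export
compute_metagenes <- function(x, signatures, ann) {
  if (!length(signatures)) stop("no signatures supplied", call. = FALSE)
  vals <- unclass(x)
  rows <- t(vapply(names(signatures), function(nm) {
    mem <- signatures[[nm]]
    absent <- setdiff(mem, rownames(vals))
    if (length(absent)) {
      message(sprintf("%s: %d member(s) absent from '%s'", nm,
                      length(absent), dataset_name(x)))
    }
    mem <- intersect(mem, rownames(vals))
    if (!length(mem)) {
      message(nm, ": no members present; emitting missing row")
      return(rep(NA_real_, ncol(vals)))
    }
    sym <- ann$feature_to_gene[mem]
    with_sym <- mem[!is.na(sym)]
    no_sym <- mem[is.na(sym)]
    per_gene <- if (length(with_sym)) {
      t(vapply(split(with_sym, sym[with_sym]), function(probes) {
        colMeans(vals[probes, , drop = FALSE])
      }, numeric(ncol(vals))))
    } else {
      NULL
    }
    colMeans(rbind(per_gene, vals[no_sym, , drop = FALSE]))
  }, numeric(ncol(vals))))
  colnames(rows) <- colnames(vals)
  structure(rows, dataset = dataset_name(x), class = "metagene_table")
}

#' Hierarchical dendrogram of metagene correlation structure
#'
#' Average-linkage hierarchical clustering of metagenes on the distance
#' 1 - Pearson r between their per-sample profiles. Constant metagene rows
#' have no defined correlation and raise an error naming the offender.
#'
#' @param m A `metagene_table` (or numeric matrix, metagenes in rows).
#' @return An `hclust` tree over the signatures (deterministic leaf order).
#' @export
metagene_dendrogram <- function(m) {
  v <- unclass(m)
  v <- v[order(rownames(v)), , drop = FALSE]
  if (nrow(v) < 2L) stop("need at least 2 metagenes", call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  if (any(!is.finite(sds) | sds == 0)) {
    stop("constant or missing metagene row(s): ",
         paste(rownames(v)[!is.finite(sds) | sds == 0], collapse = ", "),
         call. = FALSE)
  }
  stats::hclust(stats::as.dist(1 - stats::cor(t(v))), method = "average")
}

#' Write a metagene dendrogram as Newick text
#'
#' @param tree An `hclust` from [metagene_dendrogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
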