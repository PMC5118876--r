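#' All cross-dataset cluster intersections for one algorithm
#'
#' For one clustering algorithm, takes the chosen partition of every dataset
#' and computes the member intersection of every element of the Cartesian
#' product of cluster indices — with five datasets and cluster counts
#' \eqn{k_1..k_5}, \eqn{\prod_d k_d} combinations. Features absent from a
#' dataset's partition belong to no cluster there and therefore to no
#' intersection. Empty intersections count toward the total but are dropped
#' from the listing.
#'
#' @param partitions Named list over datasets of [partition()] tibbles (or
#'   named lists of cluster member sets).
#' @param algorithm Label recorded on the records.
#' @return Tibble of non-empty records (`algorithm`, `cluster_tuple`,
#'   `members` list-column, `size`), with attribute `n_total` giving
#'   \eqn{\prod_d k_d}.
#' @export
all_intersections <- function(partitions, algorithm = "kmeans") {
  sets <- lapply(partitions, function(p) {
    if (inherits(p, "partition") || is.data.frame(p)) partition_sets(p) else p
  })
  ds <- names(sets) %||% sprintf("D%d", seq_along(sets))
  ks <- lengths(sets)
  labels <- lapply(sets, function(cl) {
    names(cl) <- names(cl) %||% as.character(seq_along(cl))
    cl
  })
  # depth-first product enumeration: a branch whose running intersection is
  # already empty cannot produce a non-empty record at any deeper level, so
  # it is pruned from the listing (its tuples still count toward the total)
  acc_members <- list()
  acc_tuples <- character()
  recurse <- function(d, current, prefix) {
    if (d > length(labels)) {
      acc_members[[length(acc_members) + 1L]] <<- sort(current)
      acc_tuples[[length(acc_tuples) + 1L]] <<- paste(prefix, collapse = "|")
      return(invisible())
    }
    for (ci in seq_along(labels[[d]])) {
      nxt <- if (d == 1L) labels[[1L]][[ci]] else
        intersect(current, labels[[d]][[ci]])
      if (!length(nxt)) next
      recurse(d + 1L, nxt,
              c(prefix, sprintf("%s:%s", ds[d], names(labels[[d]])[ci])))
    }
    invisible()
  }
  recurse(1L, character(), character())
  out <- tibble::tibble(algorithm = algorithm,
                        cluster_tuple = acc_tuples,
                        members = acc_members,
                        size = lengths(acc_members))
  attr(out, "n_total") <- prod(ks)
  out
}

#' Filter intersection records by minimum size
#'
#' @param records Tibble from [all_intersections()] or [meta_consensus()].
#' @param min_size Minimum member count (inclusive: a record of exactly
#'   `min_size` members is kept). Default 10.
#' @return The filtered tibble, order preserved.
#' @export
filter_by_size <- function(records, min_size = 10) {
  stopifnot(min_size >= 1)
  dplyr::filter(records, .data$size >= min_size)
}

#' Meta-consensus of k-means and SOM intersections
#'
#' Crosses every size-filtered k-means intersection with every size-filtered
#' SOM intersection, keeps the pairwise member intersections with at least
#' `min_size` members, and de-duplicates identical member sets (keeping the
#' lexicographically first tuple label). Each surviving set — a gene set
#' common to one cluster from every dataset under both algorithms — is a
#' candidate conserved signature. When the inputs derive from true
#' partitions the resulting sets are pairwise disjoint; this is asserted.
#'
#' @param kmeans_records,som_records Size-filtered record tibbles.
#' @param min_size Minimum members for a meta-intersection. Default 10.
#' @return Tibble with `algorithm = "meta"`, `cluster_tuple` (the combined
#'   pair label), `kmeans_tuple`, `som_tuple`, `members`, `size`.
#' @export
meta_consensus <- function(kmeans_records, som_records, min_size = 10) {
  pairs <- tidyr::expand_grid(i = seq_len(nrow(kmeans_records)),
                              j = seq_len(nrow(som_records)))
  members <- purrr::map2(pairs$i, pairs$j, function(i, j) {
    sort(intersect(kmeans_records$members[[i]], som_records$members[[j]]))
  })
  keep <- lengths(members) >= min_size
  kept <- members[keep]
  out <- tibble::tibble(
    algorithm = "meta",
    kmeans_tuple = kmeans_records$cluster_tuple[pairs$i][keep],
    som_tuple = som_records$cluster_tuple[pairs$j][keep],
    members = kept,
    size = lengths(kept))
  out$cluster_tuple <- paste0("km{", out$kmeans_tuple, "} x som{",
                              out$som_tuple, "}")
  out <- out[order(out$cluster_tuple), ]
  out <- out[!duplicated(vapply(out$members, paste, "", collapse = "\r")), ]
  out <- out[order(-out$size, out$cluster_tuple), ]
  flat <- unlist(out$members, use.names = FALSE)
  if (anyDuplicated(flat)) {
    stop("meta-intersections are not pairwise disjoint; inputs were not ",
         "derived from true partitions", call. = FALSE)
  }
  dplyr::select(out, "algorithm", "cluster_tuple", "kmeans_tuple",
                "som_tuple", "members", "size")
}
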