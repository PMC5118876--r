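#' Hypergeometric upper-tail enrichment test
#'
#' Probability of drawing at least `x` annotated features when `n` features
#' are drawn without replacement from a universe of `N` features of which `K`
#' are annotated — the classical over-representation test behind gene-set
#' enrichment.
#'
#' @param N Universe size.
#' @param K Annotated features in the universe.
#' @param n Drawn set size.
#' @param x Overlap (annotated features in the drawn set).
#' @return Upper-tail p-value \eqn{P(X \ge x)}.
#' @export
hypergeometric_test <- function(N, K, n, x) {
  if (!(x >= 0 && x <= min(K, n) && min(K, n) <= N && n <= N && K <= N)) {
    stop("hypergeometric bounds violated: need 0 <= x <= min(K, n) <= N",
         call. = FALSE)
  }
  if (x == 0) return(1)
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term-enrichment table for one candidate gene set
#'
#' @param members Character vector of feature ids.
#' @param ann A [feature_annotation()].
#' @param universe Feature universe for the test.
#' @return Tibble of enrichment rows (`term_id`, `label`, `immune`, `N`, `K`,
#'   `n`, `overlap`, `p_value`, `fdr_q`), BH-adjusted within this set's term
#'   family, ordered by `p_value`.
#' @export
enrich_terms <- function(members, ann, universe) {
  members <- intersect(members, universe)
  N <- length(universe)
  rows <- purrr::map_dfr(names(ann$terms), function(tm) {
    term_u <- intersect(ann$terms[[tm]], universe)
    ov <- length(intersect(term_u, members))
    tibble::tibble(term_id = tm,
                   label = unname(ann$term_labels[tm]),
                   immune = tm %in% ann$immune_terms,
                   N = N, K = length(term_u), n = length(members),
                   overlap = ov,
                   p_value = hypergeometric_test(N, length(term_u),
                                                 length(members), ov))
  })
  rows$fdr_q <- stats::p.adjust(rows$p_value, method = "BH")
  dplyr::arrange(rows, .data$p_value, .data$term_id)
}

#' Qualify candidate meta-intersections as immune gene signatures
#'
#' A candidate becomes a signature when it passes all three criteria:
#' (i) at least `min_annotated_frac` of its members carry at least one
#' annotation term; (ii) it contains at least `min_symbols` unique gene
#' symbols; (iii) Benjamini–Hochberg adjustment of its term p-values (within
#' the candidate's term family) leaves at least one immunity-flagged term
#' with `fdr_q < fdr_cut`. The enrichment universe is the feature set the
#' candidates were drawn from, not the whole array.
#'
#' @param candidates Tibble from [meta_consensus()], or a named list of
#'   member-id vectors.
#' @param ann A [feature_annotation()].
#' @param fdr_cut FDR cut on immune terms. Default 0.05.
#' @param min_annotated_frac Minimum annotated member fraction. Default 0.5.
#' @param min_symbols Minimum unique gene symbols. Default 10.
#' @param universe Enrichment universe; defaults to the union of all
#'   candidate members.
#' @return A `signature_set`: named list (`Sig01`, ... ordered by best immune
#'   `fdr_q`) of member-id vectors, with a `qualification` attribute tibble
#'   recording every candidate's criteria.
#' @export
qualify_signatures <- function(candidates, ann, fdr_cut = 0.05,
                               min_annotated_frac = 0.5, min_symbols = 10,
                               universe = NULL) {
  if (!length(ann$terms)) stop("empty annotation", call. = FALSE)
  if (is.data.frame(candidates)) {
    sets <- candidates$members
    names(sets) <- candidates$cluster_tuple
  } else {
    sets <- candidates
    if (is.null(names(sets))) {
      names(sets) <- sprintf("candidate%02d", seq_along(sets))
    }
  }
  if (!length(sets)) stop("no candidates supplied", call. = FALSE)
  universe <- universe %||% sort(unique(unlist(sets, use.names = FALSE)))
  annotated <- unique(unlist(ann$terms, use.names = FALSE))

  qual <- purrr::map_dfr(names(sets), function(nm) {
    mem <- sets[[nm]]
    frac <- mean(mem %in% annotated)
    syms <- unique(stats::na.omit(ann$feature_to_gene[mem]))
    enr <- enrich_terms(mem, ann, universe)
    imm <- dplyr::filter(enr, .data$immune)
    best_q <- if (nrow(imm)) min(imm$fdr_q) else NA_real_
    tibble::tibble(candidate = nm, size = length(mem),
                   annotated_frac = frac, n_symbols = length(syms),
                   best_immune_q = best_q,
                   pass_annotated = frac >= min_annotated_frac,
                   pass_symbols = length(syms) >= min_symbols,
                   pass_immune = !is.na(best_q) && best_q < fdr_cut)
  })
  qual$qualified <- qual$pass_annotated & qual$pass_symbols & qual$pass_immune
  win <- dplyr::arrange(dplyr::filter(qual, .data$qualified),
                        .data$best_immune_q, .data$candidate)
  sigs <- sets[win$candidate]
  names(sigs) <- sprintf("Sig%02d", seq_along(sigs))
  win$signature <- names(sigs)
  qual <- dplyr::left_join(qual,
                           dplyr::select(win, "candidate", "signature"),
                           by = "candidate")
  structure(sigs, qualification = qual, class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set: %d signatures (sizes %s)>\n", length(x),
              paste(lengths(x), collapse = ", ")))
  invisible(x)
}
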