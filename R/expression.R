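#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric features-by-samples matrix of normalized
#' log2 intensities. Row names are feature identifiers (probe sets or gene
#' symbols), column names are sample identifiers. The container enforces the
#' invariants every downstream stage relies on: unique identifiers, finite
#' values, and at least two features and two samples.
#'
#' @param values Numeric matrix, features x samples, with row and column names.
#' @param dataset_name Single string naming the dataset (e.g. a cancer type).
#' @return An `expr_matrix`: the validated matrix with a `dataset_name`
#'   attribute.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' x <- expression_matrix(m, "toy")
#' dataset_name(x)
#' @export
expression_matrix <- function(values, dataset_name = "dataset") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs feature (row) and sample (column) names",
         call. = FALSE)
  }
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f)) {
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("expression matrix needs at least 2 features and 2 samples",
         call. = FALSE)
  }
  structure(values, dataset_name = as.character(dataset_name)[1L],
            class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
dataset_name <- function(x) attr(x, "dataset_name")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix '%s': %d features x %d samples>\n",
              dataset_name(x), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 4L))
  invisible(x)
}

#' Feature annotation container
#'
#' Bundles probe-to-gene-symbol mappings with annotation-term memberships
#' (a GO/DAVID-like term table) and the subset of terms flagged as
#' immunity-related. Used by the immune-cluster flagging and signature
#' qualification stages.
#'
#' @param feature_to_gene Named character vector: feature id -> gene symbol.
#'   `NA` marks features without a symbol. Its names define the annotated
#'   feature domain.
#' @param terms Named list: term id -> character vector of member feature ids.
#' @param term_labels Named character vector of human-readable term
#'   descriptions (optional; defaults to the term ids).
#' @param immune_terms Character vector of term ids flagged immunity-related;
#'   must be a subset of `names(terms)`.
#' @return A `feature_annotation` list.
#' @export
feature_annotation <- function(feature_to_gene, terms = list(),
                               term_labels = NULL, immune_terms = character()) {
  stopifnot(is.character(feature_to_gene), !is.null(names(feature_to_gene)))
  terms <- lapply(terms, function(m) sort(unique(as.character(m))))
  if (length(terms) && is.null(names(terms))) {
    stop("terms must be a named list", call. = FALSE)
  }
  if (!all(immune_terms %in% names(terms))) {
    stop("immune_terms must be a subset of the term domain", call. = FALSE)
  }
  if (is.null(term_labels)) {
    term_labels <- stats::setNames(names(terms), names(terms))
  }
  structure(list(feature_to_gene = feature_to_gene,
                 terms = terms,
                 term_labels = term_labels,
                 immune_terms = as.character(immune_terms)),
            class = "feature_annotation")
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat(sprintf("<feature_annotation: %d features, %d terms (%d immune)>\n",
              length(x$feature_to_gene), length(x$terms),
              length(x$immune_terms)))
  invisible(x)
}

#' Clinical table constructor
#'
#' Validates a per-sample clinical table carrying survival time, an event
#' indicator and optional stratification columns, and returns it as a tibble.
#'
#' @param data Data frame with columns `sample_id`, `time`, `event`; any
#'   further columns are treated as stratification variables.
#' @param time_unit Unit of the `time` column (free text, e.g. "years").
#' @return A `clinical_table` tibble.
#' @export
clinical_table <- function(data, time_unit = "years") {
  data <- tibble::as_tibble(data)
  req <- c("sample_id", "time", "event")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(data$sample_id)) {
    stop("duplicate sample_id in clinical table", call. = FALSE)
  }
  if (any(!is.finite(data$time)) || any(data$time < 0)) {
    stop("survival time must be finite and >= 0", call. = FALSE)
  }
  if (!all(data$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  attr(data, "time_unit") <- time_unit
  class(data) <- c("clinical_table", class(data))
  data
}
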