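#' Read an expression matrix from a delimited file
#'
#' Reads a tab-delimited matrix with feature identifiers in the first column
#' and sample identifiers in the header row. GCT files are accepted as well:
#' when the first line is the `#1.2` GCT version tag, the two header lines and
#' the `Description` column are skipped. Row and column order are preserved.
#'
#' @param path Path to a TSV or GCT file.
#' @param dataset_name Dataset label stored on the returned object; defaults
#'   to the file name without extension.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, dataset_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dataset_name <- dataset_name %||%
    sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  gct <- startsWith(first, "#1.2")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           skip = if (gct) 2L else 0L,
                           colClasses = "character", check.names = FALSE)
  ids <- raw[[1L]]
  drop <- 1L
  if (gct && ncol(raw) >= 2L && tolower(names(raw)[2L]) == "description") {
    drop <- c(1L, 2L)
  }
  body <- raw[, -drop, drop = FALSE]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate feature id(s) in ", basename(path), ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)), USE.NAMES = TRUE))
  vals <- matrix(vals, nrow = nrow(body),
                 dimnames = list(ids, names(body)))
  bad <- which(is.na(vals) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric cell at feature '%s', sample '%s' (value '%s')",
      ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]],
      as.matrix(body)[bad[1L, , drop = FALSE]]), call. = FALSE)
  }
  expression_matrix(vals, dataset_name)
}

#' Write an expression matrix as TSV
#'
#' @param x An [expression_matrix()] (or plain named numeric matrix).
#' @param path Output file path.
#' @param id_column Name for the first (feature id) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "feature_id") {
  vals <- unclass(x)
  # 17 significant digits round-trip doubles exactly
  chr <- apply(vals, 2L, function(col) sprintf("%.17g", col))
  chr <- matrix(chr, nrow = nrow(vals), dimnames = dimnames(vals))
  df <- data.frame(rownames(x), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each GMT line holds a set name, a description and one or more member
#' identifiers, tab-separated. Members are de-duplicated within a set.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; set descriptions are kept in the
#'   `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param descriptions Optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", unique(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' @param path Tab-delimited file with columns `sample_id`, `time`, `event`
#'   and optional stratification columns.
#' @param time_unit Unit of the time column.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path, time_unit = "years") {
  clinical_table(utils::read.delim(path, sep = "\t", check.names = FALSE,
                                   stringsAsFactors = FALSE), time_unit)
}

#' Write a clinical table as TSV
#' @param clin A [clinical_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(as.data.frame(clin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group map
#'
#' @param path Two-column TSV (`sample_id`, `group`).
#' @return Named character vector mapping sample id to group.
#' @export
read_group_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}
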