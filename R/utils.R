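# Internal helpers shared across stages.

# Derive a 32-bit sub-seed from a master seed and an iteration index so that
# every resampling iteration has its own reproducible RNG stream.
derive_seed <- function(seed, i) {
  # double arithmetic is exact below 2^53, so the product stays exact
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 +
                as.numeric(i)) %% 2147483629)
}

# Row-wise z-score; errors on constant rows (they carry no co-expression shape).
standardize_rows <- function(values) {
  sds <- apply(values, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("cannot standardize constant feature(s): ",
         paste(utils::head(rownames(values)[sds == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  (values - rowMeans(values)) / sds
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Significance stars using the conventional p-value coding.
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ ""
  )
}
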