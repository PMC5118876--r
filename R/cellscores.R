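#' Leukocyte reference panel
#'
#' Couples a reference expression matrix with a sample-to-group map over the
#' immune cell subsets (by default the 18 groups of [default_group_sizes()]).
#' Every sample must be mapped and every group must have at least two samples
#' so within-group variance is estimable.
#'
#' @param expression An [expression_matrix()] of the reference arrays.
#' @param sample_to_group Named character vector: sample id -> group.
#' @param groups Ordered group labels; defaults to order of first appearance.
#' @return A `reference_panel` list.
#' @export
reference_panel <- function(expression, sample_to_group, groups = NULL) {
  miss <- setdiff(colnames(expression), names(sample_to_group))
  if (length(miss)) {
    stop("unmapped sample(s): ", paste(utils::head(miss, 5L), collapse = ", "),
         call. = FALSE)
  }
  grp <- sample_to_group[colnames(expression)]
  groups <- groups %||% unique(grp)
  sizes <- table(factor(grp, levels = groups))
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  structure(list(expression = expression,
                 sample_to_group = grp,
                 groups = groups),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel: %d features, %d samples, %d groups>\n",
              nrow(x$expression), ncol(x$expression), length(x$groups)))
  invisible(x)
}

# Per-feature one-way group-means fit, vectorized over features: group means,
# pooled residual variance and residual df shared by all contrasts of a
# feature.
panel_fit <- function(panel, features) {
  xf <- unclass(panel$expression)[features, , drop = FALSE]
  g <- factor(panel$sample_to_group, levels = panel$groups)
  ng <- as.integer(table(g))
  gm <- t(apply(xf, 1L, function(row) tapply(row, g, mean)))
  fitted <- gm[, as.integer(g), drop = FALSE]
  rss <- rowSums((xf - fitted)^2)
  df <- ncol(xf) - length(panel$groups)
  list(group_means = gm, s2 = rss / df, df = df, n_per_group = ng)
}

#' Pairwise group contrasts for one feature
#'
#' Fits the one-way group-means model to a feature's reference profile and
#' returns, for every ordered group pair (g, h), the contrast coefficient
#' (mean difference g - h) and its two-sided t-test p-value using the pooled
#' residual variance shared across all contrasts of the feature.
#' Coefficients are antisymmetric by construction. With zero residual
#' variance the p-value degenerates to 0 when the means differ and 1
#' otherwise.
#'
#' @param panel A [reference_panel()].
#' @param feature A feature id present in the panel.
#' @return Tibble with `group`, `other`, `coefficient`, `p_value` for every
#'   ordered pair.
#' @export
pairwise_contrasts <- function(panel, feature) {
  if (!feature %in% rownames(panel$expression)) {
    stop("feature not in panel: ", feature, call. = FALSE)
  }
  fit <- panel_fit(panel, feature)
  G <- length(panel$groups)
  mu <- fit$group_means[1L, ]
  grid <- expand.grid(g = seq_len(G), h = seq_len(G),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$g != grid$h, ]
  coef <- mu[grid$g] - mu[grid$h]
  se <- sqrt(fit$s2 * (1 / fit$n_per_group[grid$g] +
                       1 / fit$n_per_group[grid$h]))
  p <- ifelse(se > 0,
              2 * stats::pt(-abs(coef / se), fit$df),
              ifelse(coef != 0, 0, 1))
  tibble::tibble(group = panel$groups[grid$g],
                 other = panel$groups[grid$h],
                 coefficient = unname(coef), p_value = unname(p))
}

#' Cell-type enrichment scores against a leukocyte reference panel
#'
#' For every feature, compares each group with every other group under the
#' one-way group-means model and sums, per group, the contrast coefficients
#' whose p-values survive Bonferroni correction over the unordered group
#' pairs (153 pairs for the default 18 groups): \eqn{score(f, g) = \sum_{h
#' \ne g} (\bar{x}_{fg} - \bar{x}_{fh}) \cdot 1[p_{gh} \le \alpha / {G
#' \choose 2}]}. A feature with identical group means scores 0 everywhere.
#'
#' @param panel A [reference_panel()].
#' @param features Feature ids to score (must be in the panel).
#' @param alpha Significance level before Bonferroni correction. Default
#'   0.05.
#' @return A `cell_profile`: list with `scores` (features x groups matrix),
#'   `alpha`, `n_contrasts_corrected`.
#' @export
enrichment_scores <- function(panel, features, alpha = 0.05) {
  features <- as.character(features)
  miss <- setdiff(features, rownames(panel$expression))
  if (length(miss)) {
    stop("feature(s) absent from panel: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  fit <- panel_fit(panel, features)
  G <- length(panel$groups)
  n_pairs <- choose(G, 2)
  thr <- alpha / n_pairs
  scores <- matrix(0, length(features), G,
                   dimnames = list(features, panel$groups))
  for (g in seq_len(G - 1L)) {
    for (h in seq(g + 1L, G)) {
      coef <- fit$group_means[, g] - fit$group_means[, h]
      se <- sqrt(fit$s2 * (1 / fit$n_per_group[g] + 1 / fit$n_per_group[h]))
      p <- ifelse(se > 0, 2 * stats::pt(-abs(coef / se), fit$df),
                  ifelse(coef != 0, 0, 1))
      sig <- p <= thr
      scores[, g] <- scores[, g] + coef * sig
      scores[, h] <- scores[, h] - coef * sig
    }
  }
  structure(list(scores = scores, alpha = alpha,
                 n_contrasts_corrected = n_pairs),
            class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("<cell_profile: %d features x %d groups (alpha=%g over %d pairs)>\n",
              nrow(x$scores), ncol(x$scores), x$alpha,
              x$n_contrasts_corrected))
  invisible(x)
}

#' Profile signatures across the reference-panel cell types
#'
#' Averages the per-feature cell-type enrichment scores over the members of
#' each signature, yielding a signatures x groups profile matrix; a
#' row-standardized copy for display is attached as the `"standardized"`
#' attribute. Signatures with no scored members get a row of `NA` with a
#' warning.
#'
#' @param profile A `cell_profile` from [enrichment_scores()].
#' @param signatures A `signature_set` (or named list of member-id vectors).
#' @return Numeric matrix signatures x groups with attribute
#'   `"standardized"`.
#' @export
profile_signatures <- function(profile, signatures) {
  out <- t(vapply(names(signatures), function(nm) {
    mem <- intersect(signatures[[nm]], rownames(profile$scores))
    if (!length(mem)) {
      warning("signature with no scored members: ", nm)
      return(rep(NA_real_, ncol(profile$scores)))
    }
    colMeans(profile$scores[mem, , drop = FALSE])
  }, numeric(ncol(profile$scores))))
  colnames(out) <- colnames(profile$scores)
  sds <- apply(out, 1L, stats::sd)
  std <- (out - rowMeans(out)) / ifelse(sds > 0, sds, 1)
  attr(out, "standardized") <- std
  out
}
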