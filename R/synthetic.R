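#' Default leukocyte reference-panel design
#'
#' The 18 immune cell subsets and replicate counts of the leukocyte reference
#' panel the enrichment scores are calibrated against (114 arrays in total):
#' CD8/CD4 T-cell states, memory T cells, NK-cell states, naive/memory B cells,
#' plasma cells, monocytes at three culture days, dendritic-cell states and
#' resting neutrophils.
#'
#' @return Named integer vector: group -> replicate count.
#' @export
default_group_sizes <- function() {
  c("CD8Tcell-N0-1" = 4L, "CD4Tcell-N0-1" = 3L, "CD4Tcell-Th1" = 5L,
    "CD4Tcell-Th2" = 6L, "MemoryTcell-RO-unactivated" = 3L,
    "MemoryTcell-RO-activated" = 3L, "NKcell-control" = 4L,
    "NKcell-IL2-stimulated" = 5L, "NKcell-IL15-stimulated" = 6L,
    "Bcell-naive" = 7L, "Bcell-Memory" = 8L, "PlasmaCell" = 7L,
    "Monocyte-Day0" = 12L, "Monocyte-Day1" = 12L, "Monocyte-Day7" = 12L,
    "DendriticCell-Control" = 6L, "DendriticCell-LPS-stimulated" = 6L,
    "Neutrophil-Resting" = 5L)
}

new_sim_truth <- function(conserved_modules, private_modules, background_genes,
                          seed) {
  structure(list(conserved_modules = conserved_modules,
                 private_modules = private_modules,
                 background_genes = background_genes,
                 group_markers = list(),
                 survival_beta = numeric(),
                 seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth: %d conserved modules, %d private modules, %d background genes>\n",
    length(x$conserved_modules), length(x$private_modules),
    length(x$background_genes)))
  invisible(x)
}

#' Simulate parallel tumor expression datasets with planted modules
#'
#' Generates `n_datasets` feature-by-sample log2-scale matrices over a shared
#' gene universe. Gene modules follow a single-factor model: within dataset
#' `d`, module `m` has a latent factor \eqn{f \sim N(0,1)} per sample and each
#' member gene the value \eqn{\mu_g + a_g f + \epsilon}, with loading
#' \eqn{a_g} uniform on `loading_range` and \eqn{\epsilon \sim N(0,
#' noise\_sd^2)}. Conserved modules are active in every dataset (with an
#' independent factor per dataset, so the correlation *structure*, not the
#' values, is conserved); private modules are active in exactly one dataset
#' and are plain noise elsewhere; background genes are noise everywhere.
#' Per-gene mean offsets \eqn{\mu_g \sim N(8, 1.5^2)} place values on a
#' realistic log2-intensity scale.
#'
#' Defaults mirror the study design the pipeline is validated under: five
#' datasets, 150 samples each, three conserved 40-gene modules, two private
#' modules per dataset, 300 background genes, residual noise SD 0.6.
#'
#' @param n_datasets Number of parallel datasets (>= 2).
#' @param n_samples Samples per dataset.
#' @param n_conserved Number of conserved modules shared by all datasets.
#' @param n_private Number of dataset-private modules per dataset.
#' @param module_size Genes per module (>= 10 so planted modules can survive
#'   the downstream ten-member filter).
#' @param n_background Pure-noise genes.
#' @param noise_sd Residual SD around the factor signal.
#' @param loading_range Length-2 numeric, uniform range of factor loadings.
#' @param background_sd SD of background (and inactive-module) genes.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return List with `datasets` (list of [expression_matrix()]) and `truth`
#'   (a `sim_truth` with the planted gene classes).
#' @export
simulate_datasets <- function(n_datasets = 5, n_samples = 150,
                              n_conserved = 3, n_private = 2,
                              module_size = 40, n_background = 300,
                              noise_sd = 0.6, loading_range = c(0.5, 1.5),
                              background_sd = 1, seed = 1) {
  stopifnot(n_datasets >= 2, module_size >= 10)
  conserved <- lapply(seq_len(n_conserved), function(m) {
    sprintf("CM%dG%03d", m, seq_len(module_size))
  })
  names(conserved) <- sprintf("CM%d", seq_len(n_conserved))
  private <- list()
  for (d in seq_len(n_datasets)) {
    for (m in seq_len(n_private)) {
      private[[sprintf("D%d.PM%d", d, m)]] <-
        sprintf("D%dPM%dG%03d", d, m, seq_len(module_size))
    }
  }
  background <- sprintf("BG%04d", seq_len(n_background))
  all_genes <- c(unlist(conserved, use.names = FALSE),
                 unlist(private, use.names = FALSE), background)
  if (anyDuplicated(all_genes)) {
    stop("gene-name collision across planted classes", call. = FALSE)
  }
  truth <- new_sim_truth(conserved, private, background, seed)

  set.seed(seed)
  mu <- stats::setNames(stats::rnorm(length(all_genes), 8, 1.5), all_genes)
  datasets <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    set.seed(derive_seed(seed, d))
    vals <- matrix(stats::rnorm(length(all_genes) * n_samples,
                                sd = background_sd),
                   nrow = length(all_genes),
                   dimnames = list(all_genes,
                                   sprintf("D%d_S%03d", d, seq_len(n_samples))))
    active <- c(conserved, private[startsWith(names(private),
                                              sprintf("D%d.", d))])
    for (mod in active) {
      f <- stats::rnorm(n_samples)
      a <- stats::runif(length(mod), loading_range[1L], loading_range[2L])
      vals[mod, ] <- a %o% f +
        matrix(stats::rnorm(length(mod) * n_samples, sd = noise_sd),
               nrow = length(mod))
    }
    vals <- vals + mu
    datasets[[d]] <- expression_matrix(vals, sprintf("D%d", d))
  }
  names(datasets) <- sprintf("D%d", seq_len(n_datasets))
  list(datasets = datasets, truth = truth)
}

#' Simulate a leukocyte reference expression panel
#'
#' Builds an expression matrix over `length(group_sizes)` immune-cell groups
#' with the given replicate counts. Marker genes of a group have their mean
#' elevated by `effect` in that group only; all other gene-sample values are
#' baseline plus Gaussian noise. Marker sets may be supplied (e.g. planted
#' tumor-module genes) or generated; extra unmarked features can be carried so
#' that a whole analysis universe is scorable against the panel.
#'
#' @param group_sizes Named integer vector group -> replicate count; defaults
#'   to [default_group_sizes()] (18 groups, 114 samples). Every count must be
#'   >= 2 for within-group variance estimation.
#' @param markers_per_group Markers generated per group when `marker_sets` is
#'   not supplied.
#' @param effect Mean log2 shift of a marker in its own group.
#' @param noise_sd Residual SD.
#' @param marker_sets Optional named list (group -> feature ids) overriding
#'   generated markers; names must be a subset of `names(group_sizes)`.
#' @param extra_features Additional feature ids included with no group effect.
#' @param seed Integer seed.
#' @return List: `panel` (a [reference_panel()]), `sample_to_group`,
#'   `group_markers`.
#' @export
simulate_reference_panel <- function(group_sizes = default_group_sizes(),
                                     markers_per_group = 10, effect = 3,
                                     noise_sd = 1, marker_sets = NULL,
                                     extra_features = character(), seed = 1) {
  if (any(group_sizes < 2L)) {
    stop("group(s) with fewer than 2 replicates: ",
         paste(names(group_sizes)[group_sizes < 2L], collapse = ", "),
         call. = FALSE)
  }
  groups <- names(group_sizes)
  if (is.null(marker_sets)) {
    marker_sets <- lapply(seq_along(groups), function(g) {
      sprintf("MK%02dG%02d", g, seq_len(markers_per_group))
    })
    names(marker_sets) <- groups
  } else if (!all(names(marker_sets) %in% groups)) {
    stop("marker_sets names must be reference-panel groups", call. = FALSE)
  }
  features <- unique(c(unlist(marker_sets, use.names = FALSE),
                       extra_features))
  sample_group <- rep(groups, times = group_sizes)
  sample_ids <- unlist(lapply(groups, function(g) {
    sprintf("%s_r%d", g, seq_len(group_sizes[[g]]))
  }))
  set.seed(seed)
  base <- stats::rnorm(length(features), 6, 1)
  vals <- base + matrix(stats::rnorm(length(features) * length(sample_ids),
                                     sd = noise_sd),
                        nrow = length(features),
                        dimnames = list(features, sample_ids))
  for (g in names(marker_sets)) {
    vals[marker_sets[[g]], sample_group == g] <-
      vals[marker_sets[[g]], sample_group == g, drop = FALSE] + effect
  }
  s2g <- stats::setNames(sample_group, sample_ids)
  list(panel = reference_panel(expression_matrix(vals, "reference_panel"),
                               s2g, groups = groups),
       sample_to_group = s2g,
       group_markers = marker_sets)
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with rate
#' \eqn{\lambda_0 \exp(\sum_m \beta_m z_m)} where the \eqn{z_m} are
#' row-standardized metagene values; censoring times are independent
#' exponential with rate `censor_rate` (0 disables censoring). The observed
#' time is the minimum of the two and the event indicator is 1 when the event
#' precedes censoring — the textbook non-informative-censoring setup assumed
#' by the Cox model fitted downstream.
#'
#' @param metagene_values Numeric matrix, modules x samples (a single named
#'   numeric vector is accepted for one module), with sample column names.
#' @param betas Numeric vector of per-module log-hazard coefficients, recycled
#'   against the module rows by name when named.
#' @param baseline_rate Baseline exponential event rate (> 0), per time unit.
#' @param censor_rate Exponential censoring rate (>= 0).
#' @param seed Integer seed.
#' @return A [clinical_table()] with `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(metagene_values, betas, baseline_rate = 0.1,
                              censor_rate = 0.05, seed = 1) {
  stopifnot(baseline_rate > 0, censor_rate >= 0)
  if (is.vector(metagene_values)) {
    metagene_values <- matrix(metagene_values, nrow = 1L,
                              dimnames = list("m1", names(metagene_values)))
  }
  if (!all(is.finite(metagene_values))) {
    stop("non-finite metagene value", call. = FALSE)
  }
  if (!is.null(names(betas)) && !is.null(rownames(metagene_values))) {
    betas <- betas[rownames(metagene_values)]
  }
  stopifnot(length(betas) == nrow(metagene_values))
  z <- t(scale(t(metagene_values)))
  z[is.na(z)] <- 0  # constant metagene carries no hazard signal
  lp <- as.numeric(betas %*% z)
  set.seed(seed)
  n <- ncol(metagene_values)
  t_event <- stats::rexp(n, rate = baseline_rate * exp(lp))
  t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate) else Inf
  clinical_table(tibble::tibble(
    sample_id = colnames(metagene_values),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)))
}

#' Simulate a feature annotation with immune terms matching planted modules
#'
#' Each conserved module gets one immunity-flagged term consisting exactly of
#' its genes; `n_decoy_terms` decoy terms are random draws from the gene
#' universe. A fraction `symbol_frac` of features carry a gene symbol (the
#' feature id itself), so signature-qualification criteria on symbol counts
#' and annotated fractions are exercised realistically.
#'
#' @param truth A `sim_truth` from [simulate_datasets()].
#' @param n_decoy_terms Number of random decoy terms.
#' @param symbol_frac Fraction of features given a gene symbol.
#' @param seed Integer seed.
#' @return A [feature_annotation()].
#' @export
simulate_annotation <- function(truth, n_decoy_terms = 50, symbol_frac = 0.9,
                                seed = 1) {
  universe <- c(unlist(truth$conserved_modules, use.names = FALSE),
                unlist(truth$private_modules, use.names = FALSE),
                truth$background_genes)
  set.seed(seed)
  has_symbol <- stats::runif(length(universe)) < symbol_frac
  f2g <- stats::setNames(ifelse(has_symbol, universe, NA_character_),
                         universe)
  imm <- truth$conserved_modules
  names(imm) <- sprintf("IMM%02d", seq_along(imm))
  decoy_size <- max(10L, length(imm[[1]] %||% 40L))
  decoys <- lapply(seq_len(n_decoy_terms), function(j) {
    sample(universe, min(decoy_size, length(universe)))
  })
  names(decoys) <- sprintf("DCY%03d", seq_len(n_decoy_terms))
  labels <- c(stats::setNames(sprintf("immune response module %d",
                                      seq_along(imm)), names(imm)),
              stats::setNames(sprintf("decoy process %d",
                                      seq_len(n_decoy_terms)), names(decoys)))
  feature_annotation(f2g, terms = c(imm, decoys), term_labels = labels,
                     immune_terms = names(imm))
}
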