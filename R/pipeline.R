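#' Default configuration for a fully synthetic pipeline run
#'
#' Returns the configuration [run_pipeline()] uses to validate itself on
#' planted data: five 150-sample datasets with three conserved 40-gene
#' modules, two private modules per dataset and 300 background genes at
#' noise SD 0.6; stability filtering at 100 iterations with retention 75;
#' consensus clustering with both algorithms at 100 resamples over k = 2..8;
#' and a survival stage driven by planted log-hazard coefficients
#' (-0.5, 0.4, 0) on the three conserved-module metagenes.
#'
#' @param seed Master seed for every stage.
#' @param output_dir Where artifacts are written.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
synthetic_config <- function(seed = 1, output_dir = tempfile("immunesig_")) {
  list(
    seed = seed,
    output_dir = output_dir,
    simulate = list(
      n_datasets = 5, n_samples = 150, n_conserved = 3, n_private = 2,
      module_size = 40, n_background = 300, noise_sd = 0.6,
      loading_range = c(0.5, 1.5),
      n_decoy_terms = 50, symbol_frac = 0.9,
      marker_groups = c("CD8Tcell-N0-1", "Bcell-naive", "Monocyte-Day0"),
      panel_effect = 3, panel_noise_sd = 1,
      survival_beta = c(-0.5, 0.4, 0),
      baseline_rate = 0.1, censor_rate = 0.05),
    stability = list(n_iterations = 100, sample_fraction = 0.5,
                     retention = 75, min_cluster_size = 10, corr_cut = 0.35),
    immune_flag = list(p_cut = 0.001),
    consensus = list(k_min = 2, k_max = 8, n_resamples = 100,
                     item_fraction = 0.8, consensus_floor = 0.8),
    intersect = list(min_size = 10),
    qualify = list(fdr_cut = 0.05, min_annotated_frac = 0.5,
                   min_symbols = 10),
    cellscore = list(alpha = 0.05),
    survival = list(enabled = TRUE, standardize = FALSE, strata = NULL))
}

#' Run the whole signature-discovery pipeline
#'
#' Drives every stage from a configuration list or YAML file: input
#' simulation (or loading), stability filtering, immune-cluster flagging,
#' candidate-universe union, consensus clustering with k-means and SOM,
#' cross-dataset/algorithm intersection, signature qualification, reference-
#' panel cell scoring, metagene construction and survival analysis. Per-stage
#' artifacts are written to `config$output_dir` as TSV/GMT/Newick/JSON, along
#' with `params.json` recording every parameter and seed; outputs are
#' byte-identical across runs with the same configuration and seed.
#'
#' When `config$simulate` is present, inputs are generated with the
#' synthetic-data module; otherwise `config$datasets` (named TSV paths),
#' `config$annotation` (GMT of terms + TSV feature-to-gene map +
#' immune-term ids), `config$panel` and `config$clinical` supply them.
#'
#' @param config Configuration list (see [synthetic_config()]) or path to a
#'   YAML file with the same structure.
#' @return Invisibly, a list with every intermediate object (`datasets`,
#'   `truth`, `stable`, `immune_flags`, `candidate_universe`, `consensus`,
#'   `chosen_k`, `ari`, `intersections`, `meta`, `signatures`, `cell_scores`,
#'   `signature_profiles`, `metagenes`, `survival`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir %||% tempfile("immunesig_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # ---- inputs ------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    sim <- simulate_datasets(
      n_datasets = sc$n_datasets %||% 5, n_samples = sc$n_samples %||% 150,
      n_conserved = sc$n_conserved %||% 3, n_private = sc$n_private %||% 2,
      module_size = sc$module_size %||% 40,
      n_background = sc$n_background %||% 300,
      noise_sd = sc$noise_sd %||% 0.6,
      loading_range = sc$loading_range %||% c(0.5, 1.5),
      seed = derive_seed(seed, 101L))
    datasets <- sim$datasets
    truth <- sim$truth
    ann <- simulate_annotation(truth, n_decoy_terms = sc$n_decoy_terms %||% 50,
                               symbol_frac = sc$symbol_frac %||% 0.9,
                               seed = derive_seed(seed, 102L))
    marker_groups <- sc$marker_groups %||%
      names(default_group_sizes())[seq_along(truth$conserved_modules)]
    marker_sets <- stats::setNames(truth$conserved_modules[
      seq_along(marker_groups)], marker_groups)
    other_genes <- setdiff(names(ann$feature_to_gene),
                           unlist(marker_sets, use.names = FALSE))
    pan <- simulate_reference_panel(
      effect = sc$panel_effect %||% 3, noise_sd = sc$panel_noise_sd %||% 1,
      marker_sets = marker_sets, extra_features = other_genes,
      seed = derive_seed(seed, 103L))
    truth$group_markers <- pan$group_markers
    betas <- sc$survival_beta %||% rep(0, length(truth$conserved_modules))
    truth$survival_beta <- stats::setNames(
      betas[seq_along(truth$conserved_modules)],
      names(truth$conserved_modules))
    clinical <- lapply(seq_along(datasets), function(d) {
      mg_true <- t(vapply(truth$conserved_modules, function(mod) {
        colMeans(unclass(datasets[[d]])[mod, , drop = FALSE])
      }, numeric(ncol(datasets[[d]]))))
      simulate_survival(mg_true, truth$survival_beta,
                        baseline_rate = sc$baseline_rate %||% 0.1,
                        censor_rate = sc$censor_rate %||% 0.05,
                        seed = derive_seed(seed, 104L + d))
    })
    names(clinical) <- names(datasets)
    panel <- pan$panel
  } else {
    if (is.null(config$datasets)) {
      stop("stage 'inputs': no datasets configured", call. = FALSE)
    }
    datasets <- lapply(names(config$datasets), function(nm) {
      read_expression(config$datasets[[nm]], nm)
    })
    names(datasets) <- names(config$datasets)
    ann <- load_annotation_config(config$annotation)
    panel <- if (!is.null(config$panel)) {
      reference_panel(read_expression(config$panel$expression, "panel"),
                      read_group_map(config$panel$groups))
    }
    clinical <- if (!is.null(config$clinical)) {
      lapply(config$clinical, read_clinical)
    }
  }
  note("seed: %d", seed)
  note("datasets: %s", paste(names(datasets), collapse = ", "))

  # ---- optional probe collapsing ----------------------------------------
  probe_groups <- NULL
  working <- datasets
  if (isTRUE(config$collapse$enabled)) {
    collapsed <- lapply(datasets, collapse_probes, ann = ann,
                        r_threshold = config$collapse$r_threshold %||% 0.4)
    working <- lapply(collapsed, `[[`, "matrix")
    probe_groups <- lapply(collapsed, `[[`, "groups")
    note("collapse: r_threshold=%g", config$collapse$r_threshold %||% 0.4)
  }

  # ---- stability filter + immune flags ----------------------------------
  st <- config$stability %||% list()
  stable <- lapply(seq_along(working), function(d) {
    stability_filter(working[[d]],
                     n_iterations = st$n_iterations %||% 1000,
                     sample_fraction = st$sample_fraction %||% 0.5,
                     retention = st$retention %||% 750,
                     seed = derive_seed(seed, 200L + d),
                     min_cluster_size = st$min_cluster_size %||% 10,
                     corr_cut = st$corr_cut %||% 0.35)
  })
  names(stable) <- names(working)
  flags <- lapply(stable, flag_immune_clusters, ann = ann,
                  p_cut = config$immune_flag$p_cut %||% 0.001)
  for (d in names(stable)) {
    tab <- tibble::tibble(
      cluster = rep(names(stable[[d]]$clusters),
                    lengths(stable[[d]]$clusters)),
      feature = unlist(stable[[d]]$clusters, use.names = FALSE),
      immune_flagged = rep(names(stable[[d]]$clusters) %in% flags[[d]],
                           lengths(stable[[d]]$clusters)))
    utils::write.table(tab, file.path(out_dir,
                                      sprintf("stable_clusters_%s.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- candidate universe -----------------------------------------------
  flagged_sets <- lapply(names(stable), function(d) {
    stable[[d]]$clusters[flags[[d]]]
  })
  universe <- take_union(flagged_sets, probe_groups)
  if (!length(universe)) {
    stop("stage 'union': no immune-flagged stable clusters", call. = FALSE)
  }
  note("candidate universe: %d features", length(universe))
  writeLines(universe, file.path(out_dir, "candidate_universe.txt"))

  # ---- consensus clustering ---------------------------------------------
  cc <- config$consensus %||% list()
  k_range <- seq(cc$k_min %||% 2, cc$k_max %||% 10)
  consensus <- list()
  chosen_k <- list()
  parts <- list(kmeans = list(), som = list())
  for (alg in c("kmeans", "som")) {
    for (d in names(datasets)) {
      xd <- datasets[[d]]
      xu <- expression_matrix(unclass(xd)[intersect(universe, rownames(xd)),
                                          , drop = FALSE], d)
      res <- consensus_cluster(xu, algorithm = alg, k_range = k_range,
                               n_resamples = cc$n_resamples %||% 500,
                               item_fraction = cc$item_fraction %||% 0.8,
                               seed = derive_seed(
                                 seed, 300L + match(d, names(datasets)) +
                                   100L * (alg == "som")))
      kk <- select_k(res, consensus_floor = cc$consensus_floor %||% 0.8)
      consensus[[paste(d, alg, sep = ".")]] <- res
      chosen_k[[paste(d, alg, sep = ".")]] <- kk
      parts[[alg]][[d]] <- res[[as.character(kk)]]$consensus_partition
      note("consensus %s/%s: k=%d", d, alg, kk)
    }
  }
  summ <- purrr::map_dfr(names(consensus), function(nm) {
    dplyr::mutate(tidy.consensus_set(consensus[[nm]]), run = nm,
                  selected = .data$k == chosen_k[[nm]])
  })
  utils::write.table(summ, file.path(out_dir, "consensus_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ari <- vapply(names(datasets), function(d) {
    adjusted_rand(parts$kmeans[[d]], parts$som[[d]])
  }, 0)
  utils::write.table(tibble::tibble(dataset = names(ari), ari = ari),
                     file.path(out_dir, "ari.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- intersections + meta-consensus -----------------------------------
  min_size <- config$intersect$min_size %||% 10
  km_rec <- filter_by_size(all_intersections(parts$kmeans, "kmeans"),
                           min_size)
  som_rec <- filter_by_size(all_intersections(parts$som, "som"), min_size)
  meta <- meta_consensus(km_rec, som_rec, min_size)
  note("intersections: kmeans %d (>=%d), som %d (>=%d), meta %d",
       nrow(km_rec), min_size, nrow(som_rec), min_size, nrow(meta))

  # ---- qualification -----------------------------------------------------
  qc <- config$qualify %||% list()
  signatures <- qualify_signatures(
    meta, ann, fdr_cut = qc$fdr_cut %||% 0.05,
    min_annotated_frac = qc$min_annotated_frac %||% 0.5,
    min_symbols = qc$min_symbols %||% 10, universe = universe)
  utils::write.table(attr(signatures, "qualification"),
                     file.path(out_dir, "qualification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_sets(unclass(signatures)[seq_along(signatures)],
                  file.path(out_dir, "signatures.gmt"))
  note("qualified signatures: %d", length(signatures))

  # ---- cell scores --------------------------------------------------------
  cell_scores <- NULL
  sig_profiles <- NULL
  if (!is.null(panel) && length(signatures)) {
    scoreable <- intersect(universe, rownames(panel$expression))
    cell_scores <- enrichment_scores(panel, scoreable,
                                     alpha = config$cellscore$alpha %||% 0.05)
    write_expression(cell_scores$scores,
                     file.path(out_dir, "cell_scores.tsv"))
    sig_profiles <- profile_signatures(cell_scores, signatures)
    write_expression(sig_profiles,
                     file.path(out_dir, "signature_profiles.tsv"),
                     id_column = "signature")
  }

  # ---- metagenes + survival ----------------------------------------------
  metagenes <- NULL
  surv <- NULL
  if (length(signatures)) {
    metagenes <- lapply(datasets, compute_metagenes,
                        signatures = signatures, ann = ann)
    for (d in names(metagenes)) {
      write_expression(unclass(metagenes[[d]]),
                       file.path(out_dir, sprintf("metagenes_%s.tsv", d)),
                       id_column = "signature")
      if (nrow(metagenes[[d]]) >= 2L) {
        write_dendrogram(metagene_dendrogram(metagenes[[d]]),
                         file.path(out_dir,
                                   sprintf("metagene_dendrogram_%s.nwk", d)))
      }
    }
    if (isTRUE(config$survival$enabled %||% TRUE)) {
      if (is.null(clinical)) {
        stop("stage 'survival': no clinical tables configured",
             call. = FALSE)
      }
      surv <- purrr::map_dfr(names(metagenes), function(d) {
        dplyr::mutate(
          stratified_survival(metagenes[[d]], clinical[[d]],
                              strata_spec = config$survival$strata,
                              standardize =
                                isTRUE(config$survival$standardize)),
          dataset = d, .before = 1L)
      })
      utils::write.table(surv, file.path(out_dir, "survival.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  params <- config
  params$output_dir <- NULL
  jsonlite::write_json(params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, log_path)

  invisible(list(datasets = datasets, truth = truth, annotation = ann,
                 stable = stable, immune_flags = flags,
                 candidate_universe = universe, consensus = consensus,
                 chosen_k = chosen_k, ari = ari,
                 intersections = list(kmeans = km_rec, som = som_rec),
                 meta = meta, signatures = signatures,
                 cell_scores = cell_scores,
                 signature_profiles = sig_profiles,
                 metagenes = metagenes, survival = surv,
                 clinical = if (exists("clinical")) clinical,
                 paths = list(dir = out_dir,
                              signatures = file.path(out_dir,
                                                     "signatures.gmt"),
                              survival = file.path(out_dir,
                                                   "survival.tsv"))))
}

# Load a feature annotation from configured files: a GMT of terms, a TSV
# feature-to-gene map (feature_id, gene) and a list/file of immune term ids.
load_annotation_config <- function(acfg) {
  if (is.null(acfg)) stop("stage 'inputs': no annotation configured",
                          call. = FALSE)
  terms <- read_gene_sets(acfg$terms)
  map <- utils::read.delim(acfg$feature_to_gene, sep = "\t",
                           stringsAsFactors = FALSE)
  f2g <- stats::setNames(as.character(map[[2L]]), map[[1L]])
  f2g[f2g == ""] <- NA_character_
  imm <- acfg$immune_terms
  if (length(imm) == 1L && file.exists(imm)) imm <- readLines(imm)
  feature_annotation(f2g, terms = terms,
                     term_labels = attr(terms, "descriptions"),
                     immune_terms = imm)
}
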