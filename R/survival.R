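#' Univariate Cox proportional-hazards association for one metagene
#'
#' Fits a Cox model with the metagene as a single continuous explanatory
#' variable (Efron approximation for tied event times, via
#' [survival::coxph()]), and reports the hazard ratio per unit metagene with
#' its Wald 95% confidence interval and p-value. The `inverse` flag marks
#' hazard ratios above 1, i.e. a higher metagene associated with poorer
#' outcome.
#'
#' @param m Named numeric vector of per-sample metagene values.
#' @param clin A [clinical_table()].
#' @param metagene Label recorded in the report row.
#' @param stratum Stratum label recorded in the report row.
#' @param standardize Standardize the metagene before fitting (for
#'   cross-dataset comparability of hazard ratios). Default `FALSE`: the
#'   covariate is used raw.
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @return One-row tibble: `metagene`, `stratum`, `n`, `events`, `beta`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_value`, `inverse`, `stars`.
#' @export
cox_univariate <- function(m, clin, metagene = "metagene", stratum = "all",
                           standardize = FALSE, ties = "efron") {
  ids <- intersect(names(m), clin$sample_id)
  if (!length(ids)) stop("no overlapping sample ids", call. = FALSE)
  cl <- clin[match(ids, clin$sample_id), ]
  z <- as.numeric(m[ids])
  if (sum(cl$event) < 1) stop("no events in stratum", call. = FALSE)
  if (standardize) z <- (z - mean(z)) / stats::sd(z)
  fit <- survival::coxph(survival::Surv(cl$time, cl$event) ~ z, ties = ties)
  s <- summary(fit)
  tibble::tibble(
    metagene = metagene, stratum = stratum,
    n = length(ids), events = as.integer(sum(cl$event)),
    beta = unname(stats::coef(fit)),
    hazard_ratio = unname(exp(stats::coef(fit))),
    ci_low = unname(s$conf.int[1L, "lower .95"]),
    ci_high = unname(s$conf.int[1L, "upper .95"]),
    p_value = unname(s$coefficients[1L, "Pr(>|z|)"]),
    inverse = unname(exp(stats::coef(fit))) > 1,
    stars = p_stars(unname(s$coefficients[1L, "Pr(>|z|)"])))
}

# Deterministic tertile binning by sample quantiles, ties to the lower bin.
tertile_bins <- function(x) {
  qs <- stats::quantile(x, c(1, 2) / 3, names = FALSE)
  cut_lab <- ifelse(x <= qs[1L], "low", ifelse(x <= qs[2L], "med", "high"))
  factor(cut_lab, levels = c("low", "med", "high"))
}

#' Stratified metagene-survival associations
#'
#' Runs [cox_univariate()] for every metagene overall and within every
#' requested stratum. Categorical stratifiers contribute one stratum per
#' level; continuous stratifiers are binned into sample-quantile tertiles
#' (low/med/high, ties to the lower bin). Strata without events yield a row
#' with missing estimates rather than an error.
#'
#' @param m A `metagene_table` (metagenes x samples).
#' @param clin A [clinical_table()] whose extra columns hold the
#'   stratifiers.
#' @param strata_spec Optional character vector of stratifier column names,
#'   or a named list mapping column name to `"levels"` (categorical) or
#'   `"tertiles"` (continuous binning). `NULL` runs only the overall
#'   analysis.
#' @param standardize Passed to [cox_univariate()].
#' @return A `survival_report` tibble: one row per (metagene, stratum), with
#'   significance stars coded `***` (p <= 0.001), `**` (p <= 0.01), `*`
#'   (p <= 0.05).
#' @export
stratified_survival <- function(m, clin, strata_spec = NULL,
                                standardize = FALSE) {
  v <- unclass(m)
  if (is.character(strata_spec)) {
    strata_spec <- stats::setNames(as.list(rep("auto", length(strata_spec))),
                                   strata_spec)
  }
  for (col in names(strata_spec)) {
    if (!col %in% names(clin)) {
      stop("stratifier column absent from clinical table: ", col,
           call. = FALSE)
    }
  }
  strata <- list(all = rep(TRUE, nrow(clin)))
  for (col in names(strata_spec)) {
    mode <- strata_spec[[col]]
    vals <- clin[[col]]
    if (mode == "tertiles" || (mode == "auto" && is.numeric(vals))) {
      bins <- tertile_bins(vals)
      for (lv in levels(bins)) {
        strata[[sprintf("%s=%s", col, lv)]] <- !is.na(bins) & bins == lv
      }
    } else {
      for (lv in sort(unique(stats::na.omit(vals)))) {
        strata[[sprintf("%s=%s", col, lv)]] <- !is.na(vals) & vals == lv
      }
    }
  }
  empty_row <- function(mg, st, n, ev) {
    tibble::tibble(metagene = mg, stratum = st, n = n, events = ev,
                   beta = NA_real_, hazard_ratio = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   p_value = NA_real_, inverse = NA, stars = "")
  }
  out <- purrr::map_dfr(rownames(v), function(mg) {
    purrr::map_dfr(names(strata), function(st) {
      sel <- clin$sample_id[strata[[st]]]
      sel <- intersect(sel, colnames(v))
      sub <- clin[match(sel, clin$sample_id), ]
      if (length(sel) < 3L || sum(sub$event) < 1 ||
          stats::sd(v[mg, sel]) == 0) {
        message(sprintf("stratum '%s': too few samples/events for %s",
                        st, mg))
        return(empty_row(mg, st, length(sel), as.integer(sum(sub$event))))
      }
      cox_univariate(stats::setNames(v[mg, sel], sel), sub,
                     metagene = mg, stratum = st, standardize = standardize)
    })
  })
  class(out) <- c("survival_report", class(out))
  out
}

#' @export
tidy.survival_report <- function(x, ...) tibble::as_tibble(x)

#' One-line summary of a survival report
#' @param x A `survival_report`.
#' @param ... Unused.
#' @return Tibble with metagene count, strata count and the number of rows
#'   significant at 0.05.
#' @export
glance.survival_report <- function(x, ...) {
  tibble::tibble(n_metagenes = dplyr::n_distinct(x$metagene),
                 n_strata = dplyr::n_distinct(x$stratum),
                 n_significant = sum(x$p_value <= 0.05, na.rm = TRUE))
}

#' Turn an immunesig result into a tidy tibble
#'
#' Broom-style generic: methods exist for `survival_report` and
#' `consensus_set` objects.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of an immunesig result
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy.default <- function(x, ...) tibble::as_tibble(x)
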