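#' Umbrella configuration for a pipeline run
#'
#' @param sim A [sim_config()] (used when no dataset is supplied).
#' @param hmrf An [hmrf_config()].
#' @param filter A [case_filter_config()].
#' @param overlay Attach synthetic tumour/normal read counts and compute
#'   VAF-based interaction weights?
#' @param overlay_args Arguments passed on to [overlay_read_counts()].
#' @param filter_singular Run the singular-case filter (and refit) before the
#'   association test?
#' @param mode Significance mode, see [declare_significance()].
#' @param seed Master seed; every stage draws from a named substream.
#' @param output_dir Optional directory for on-disk artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), hmrf = hmrf_config(),
                       filter = case_filter_config(), overlay = TRUE,
                       overlay_args = list(), filter_singular = TRUE,
                       mode = c("simulation", "exome"), seed = NULL,
                       output_dir = NULL) {
  structure(list(sim = sim, hmrf = hmrf, filter = filter, overlay = overlay,
                 overlay_args = overlay_args,
                 filter_singular = filter_singular, mode = match.arg(mode),
                 seed = seed, output_dir = output_dir),
            class = "run_config")
}

#' Run the full burden-test pipeline on one dataset
#'
#' Stages: simulate (or ingest) the dataset, overlay read counts and derive
#' per-site VAF statistics, sub-clones and interaction weights, partition the
#' site axis into four-gamete-compatible intervals, fit the HMRF selection
#' model, remove singular cases and refit, and run the collapsing association
#' test on the selected variants.
#'
#' @param cfg A [run_config()].
#' @param ds Optional `rare_dataset`; simulated from `cfg$sim` when `NULL`.
#' @return An object of class `rareburden_result` with components `dataset`,
#'   `stats`, `weights`, `intervals`, `fit`, `filter_report`, `test`.
#' @examples
#' res <- rareburden_pipeline(run_config(
#'   sim = sim_config(n_cases = 200, n_controls = 200, n_sites = 30,
#'                    n_causal = 10, group_par = 0.05),
#'   overlay = FALSE, seed = 7))
#' res$test
#' @export
rareburden_pipeline <- function(cfg = run_config(), ds = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  seed <- cfg$seed
  if (is.null(ds))
    ds <- generate_dataset(cfg$sim, seed = substream_seed(seed, "simulate"))
  stats <- NULL; weights <- NULL; subclones <- NULL
  if (cfg$overlay && is.null(ds$read_counts))
    ds <- do.call(overlay_read_counts,
                  c(list(ds = ds, seed = substream_seed(seed, "overlay")),
                    cfg$overlay_args))
  intervals <- find_compatible_intervals(ds)
  if (!is.null(ds$read_counts)) {
    stats <- site_stats(ds)
    site_type <- ds$site_type %||% rep("germline", ncol(ds$genotypes))
    somatic <- which(site_type == "somatic" & stats$informative)
    if (length(somatic) >= 1) {
      cl <- cluster_subclones(stats$tumor_vaf_mean[somatic])
      subclones <- tibble(site = seq_len(ncol(ds$genotypes)), cluster = 1L)
      subclones$cluster[somatic] <- cl$cluster
    }
    weights <- interaction_weights(stats, intervals, subclones, site_type)
  }
  fit <- fit_hmrf(ds, weights = weights, intervals = intervals,
                  config = cfg$hmrf)
  filter_report <- NULL
  ds_used <- ds
  if (cfg$filter_singular) {
    fc <- filter_cases(ds, fit, cfg$filter,
                       seed = substream_seed(seed, "filter"))
    filter_report <- fc$report
    if (any(fc$report$removed)) {
      ds_used <- fc$dataset
      fit <- fit_hmrf(ds_used, weights = weights, intervals = intervals,
                      config = cfg$hmrf)
    }
  }
  test <- assoc_test(ds_used, fit, mode = cfg$mode)
  res <- structure(
    list(dataset = ds, dataset_used = ds_used, stats = stats,
         weights = weights, intervals = intervals, fit = fit,
         filter_report = filter_report, test = test, config = cfg,
         seed = seed),
    class = "rareburden_result")
  if (!is.null(cfg$output_dir)) write_result_artifacts(res, cfg$output_dir)
  res
}

#' @export
print.rareburden_result <- function(x, ...) {
  cat("<rareburden_result>\n")
  print(x$fit)
  cat("  burden test: p = ", signif(x$test$p_value, 3),
      if (x$test$significant) " (significant)" else " (not significant)",
      " on ", x$test$n_selected, " selected variants\n", sep = "")
  invisible(x)
}

#' Replicate simulation study across PAR configurations
#'
#' Generates `n_datasets` fixed-number datasets per `group_par` value, runs
#' the full pipeline on each, and aggregates power and the selection-level
#' type-I/type-II error rates with [evaluate_replicates()].
#'
#' @param group_pars Group PAR values (the study grid is 0.02-0.05).
#' @param n_datasets Replicates per configuration.
#' @param cfg A [run_config()] template; its `sim` is re-parameterised per
#'   configuration.
#' @param n_causal Number of preset causal variants.
#' @param seed Master seed; each dataset uses a named substream.
#' @return List with `results` (one row per dataset) and `summary` (one row
#'   per configuration), both tibbles.
#' @export
run_simulation_study <- function(group_pars = c(0.02, 0.03, 0.04, 0.05),
                                 n_datasets = 100, cfg = run_config(),
                                 n_causal = 50, seed = NULL) {
  results <- purrr::map_dfr(group_pars, function(par) {
    purrr::map_dfr(seq_len(n_datasets), function(i) {
      sim <- cfg$sim
      sim$group_par <- par
      sim$n_causal <- as.integer(n_causal)
      cfg_i <- cfg
      cfg_i$sim <- sim
      cfg_i$seed <- substream_seed(seed, paste0("par", par * 1000, "_", i))
      res <- rareburden_pipeline(cfg_i)
      tibble(group_par = par, dataset = i,
             significant = res$test$significant,
             p_value = res$test$p_value,
             n_selected = res$test$n_selected,
             selected = res$test$selected,
             truth = list(res$dataset$causal_truth))
    })
  })
  summary <- results |>
    dplyr::group_by(.data$group_par) |>
    dplyr::group_modify(~ evaluate_replicates(.x)) |>
    dplyr::ungroup()
  structure(list(results = results, summary = summary),
            class = "rareburden_study")
}

#' @export
print.rareburden_study <- function(x, ...) {
  cat("<rareburden_study>\n")
  print(x$summary)
  invisible(x)
}

#' Null-model study of the dataset-level false-report rate
#'
#' Generates null datasets (independent Bernoulli mutations, random labels),
#' runs the pipeline on each, and reports how often a dataset is declared
#' significant. Read-count overlay is skipped: the null model carries no VAF
#' structure.
#'
#' @param n_datasets Number of null datasets.
#' @param n_samples,n_sites,mut_prob Null-model parameters.
#' @param cfg A [run_config()] template.
#' @param seed Master seed.
#' @return List with `results` (per dataset) and `rate` (the significant
#'   fraction).
#' @export
run_null_study <- function(n_datasets = 1000, n_samples = 1000,
                           n_sites = 100, mut_prob = 0.005,
                           cfg = run_config(overlay = FALSE), seed = NULL) {
  results <- purrr::map_dfr(seq_len(n_datasets), function(i) {
    ds <- generate_null_dataset(n_samples, n_sites, mut_prob,
                                seed = substream_seed(seed, paste0("null", i)))
    cfg_i <- cfg
    cfg_i$seed <- substream_seed(seed, paste0("nullrun", i))
    res <- rareburden_pipeline(cfg_i, ds = ds)
    tibble(dataset = i, significant = res$test$significant,
           p_value = res$test$p_value, n_selected = res$test$n_selected)
  })
  list(results = results, rate = mean(results$significant))
}
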