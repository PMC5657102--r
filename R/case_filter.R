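#' Case-filter configuration
#'
#' @param singular_variant_threshold A case is removed when its (bootstrap
#'   averaged) count of aberrant variants exceeds this user-set number.
#' @param bootstrap_reps Bootstrap replicates over the shortlist.
#' @param shortlist_size Number L of most-typical cases used as the bootstrap
#'   pool; `NULL` means half of the cases.
#' @return An object of class `case_filter_config`.
#' @export
case_filter_config <- function(singular_variant_threshold = 5,
                               bootstrap_reps = 50, shortlist_size = NULL) {
  stopifnot(singular_variant_threshold >= 1, bootstrap_reps >= 1,
            is.null(shortlist_size) || shortlist_size >= 1)
  structure(list(singular_variant_threshold = singular_variant_threshold,
                 bootstrap_reps = bootstrap_reps,
                 shortlist_size = shortlist_size),
            class = "case_filter_config")
}

# Per-sample per-site carrier probability under the fitted model: a blend of
# the elevated component (label-specific rate) and the background component,
# weighted by the site's region posterior.
carrier_prob_matrix <- function(fit, ds) {
  n <- fit$n_case + fit$n_control
  q_case_e <- min(fit$params$rate_e * n * fit$params$w1 / fit$n_case, 0.99)
  q_ctrl_e <- min(fit$params$rate_e * n * (1 - fit$params$w1) /
                    max(fit$n_control, 1), 0.99)
  q_b <- min(fit$params$rate_bg, 0.99)
  r <- fit$r
  is_case <- ds$labels == "case"
  p_case <- r * q_case_e + (1 - r) * q_b
  p_ctrl <- r * q_ctrl_e + (1 - r) * q_b
  p <- matrix(rep(p_ctrl, each = nrow(ds$genotypes)),
              nrow(ds$genotypes), length(r))
  p[is_case, ] <- matrix(rep(p_case, each = sum(is_case)),
                         sum(is_case), length(r))
  pmin(pmax(p, 1e-6), 1 - 1e-6)
}

#' Posterior probability of each observed genotype
#'
#' The per-sample per-site posterior \eqn{\zeta(G_{i,s})} of the observed
#' carrier status under the fitted model, normalised over the two genotype
#' alternatives so that \eqn{\zeta(G) + \zeta(\bar G) = 1}. A variant whose
#' observed genotype is less probable than its complement
#' (\eqn{\zeta < 1/2}) has a divergent feature pattern.
#'
#' @param fit An `hmrf_fit`.
#' @param ds The `rare_dataset` the model was fitted to.
#' @return Matrix (samples x sites) of \eqn{\zeta} values in (0, 1).
#' @export
posterior_zeta <- function(fit, ds) {
  stopifnot(inherits(fit, "hmrf_fit"), inherits(ds, "rare_dataset"))
  p <- carrier_prob_matrix(fit, ds)
  carrier <- carrier_matrix(ds)
  zeta <- ifelse(carrier == 1L, p, 1 - p)
  dimnames(zeta) <- dimnames(ds$genotypes)
  zeta
}

#' Count aberrant variants per sample
#'
#' Number of sites at which the observed genotype's posterior is smaller than
#' its complement's (\eqn{\zeta(G) < \zeta(\bar G)}).
#'
#' @inheritParams posterior_zeta
#' @param samples Optional subset of sample names or indices.
#' @return Named integer vector of flagged-variant counts.
#' @export
flag_singular_variants <- function(fit, ds, samples = NULL) {
  zeta <- posterior_zeta(fit, ds)
  counts <- rowSums(zeta < 0.5)
  if (!is.null(samples)) counts <- counts[samples]
  counts
}

#' Remove singular cases
#'
#' Shortlists the L most-typical cases (largest total log posterior of their
#' observed genotypes), bootstrap-resamples the shortlist to re-estimate the
#' per-site typical carrier frequency, recomputes each case's aberrant-variant
#' count against every bootstrap replicate, and removes cases whose average
#' count exceeds the threshold. Controls are never removed. Deterministic
#' under a fixed seed.
#'
#' @param ds A `rare_dataset`.
#' @param fit The `hmrf_fit` for `ds`.
#' @param cfg A [case_filter_config()].
#' @param seed Optional integer seed for the bootstrap.
#' @return List with the filtered `dataset` and a `report` tibble
#'   (`sample`, `flagged`, `removed`).
#' @export
filter_cases <- function(ds, fit, cfg = case_filter_config(), seed = NULL) {
  stopifnot(inherits(ds, "rare_dataset"), inherits(fit, "hmrf_fit"))
  is_case <- ds$labels == "case"
  n_cases <- sum(is_case)
  if (n_cases == 0) abort("No cases in the dataset.")
  zeta <- posterior_zeta(fit, ds)
  typicality <- rowSums(log(zeta))
  case_idx <- which(is_case)
  l_size <- min(cfg$shortlist_size %||% max(1L, n_cases %/% 2L), n_cases)
  shortlist <- case_idx[order(typicality[case_idx],
                              decreasing = TRUE)][seq_len(l_size)]
  carrier <- carrier_matrix(ds)
  flags <- with_seed(seed, {
    reps <- purrr::map(seq_len(cfg$bootstrap_reps), function(rep) {
      boot <- shortlist[sample.int(l_size, l_size, replace = TRUE)]
      p_boot <- (colSums(carrier[boot, , drop = FALSE]) + 0.5) / (l_size + 1)
      p_obs <- sweep(carrier[case_idx, , drop = FALSE], 2, p_boot, function(g, p)
        ifelse(g == 1L, p, 1 - p))
      rowSums(p_obs < 0.5)
    })
    Reduce(`+`, reps) / cfg$bootstrap_reps
  })
  removed <- flags > cfg$singular_variant_threshold
  if (all(removed))
    abort("The filter removed every case; check `singular_variant_threshold`.")
  report <- tibble(sample = rownames(ds$genotypes)[case_idx],
                   flagged = as.numeric(flags), removed = removed)
  keep <- rep(TRUE, nrow(ds$genotypes))
  keep[case_idx[removed]] <- FALSE
  out <- ds
  out$genotypes <- ds$genotypes[keep, , drop = FALSE]
  out$labels <- ds$labels[keep]
  if (!is.null(ds$read_counts))
    out$read_counts <- purrr::map(ds$read_counts, function(mat)
      mat[keep, , drop = FALSE])
  list(dataset = out, report = report)
}
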