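#' Collapse selected variants into a virtual locus
#'
#' A sample is a carrier of the virtual locus iff it carries at least one of
#' the selected variants; the carrier counts are tabulated by case/control
#' label into a 2 x 2 table.
#'
#' @param ds A `rare_dataset`.
#' @param selected 1-based site indices (e.g. `fit$selected_sites`).
#' @return A 2 x 2 matrix (rows carrier/non-carrier, columns case/control).
#'   An empty selection gives an all-zero carrier row.
#' @export
collapse_variants <- function(ds, selected) {
  stopifnot(inherits(ds, "rare_dataset"))
  carrier <- if (length(selected))
    as.integer(rowSums(carrier_matrix(ds)[, selected, drop = FALSE]) > 0)
  else integer(nrow(ds$genotypes))
  is_case <- ds$labels == "case"
  tab <- matrix(c(sum(carrier[is_case]), sum(carrier[!is_case]),
                  sum(is_case) - sum(carrier[is_case]),
                  sum(!is_case) - sum(carrier[!is_case])),
                2, 2, byrow = TRUE,
                dimnames = list(c("carrier", "non_carrier"),
                                c("case", "control")))
  tab
}

#' Burden test on a collapsed carrier table
#'
#' Pearson's 1-df chi-squared test (without continuity correction) on the
#' 2 x 2 carrier table, falling back to Fisher's exact test when any expected
#' cell drops below 5. Degenerate margins (no carriers anywhere, or
#' carriers everywhere) return p = 1.
#'
#' @param table 2 x 2 matrix from [collapse_variants()].
#' @return One-row tibble: `statistic`, `p_value`, `method`.
#' @export
burden_test <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(tibble(statistic = 0, p_value = 1, method = "degenerate"))
  ch <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(ch$expected < 5)) {
    tibble(statistic = unname(ch$statistic),
           p_value = fisher.test(table)$p.value, method = "fisher")
  } else {
    tibble(statistic = unname(ch$statistic),
           p_value = unname(ch$p.value), method = "chisq")
  }
}

#' Declare dataset or gene significance
#'
#' Simulation mode uses the replicate-table threshold P < 0.05; exome mode
#' uses the Bonferroni threshold P < 2.5e-6 (0.05 over 20,000 genes). Both
#' comparisons are strict.
#'
#' @param p P-value(s).
#' @param mode `"simulation"` or `"exome"`.
#' @return Logical vector.
#' @export
declare_significance <- function(p, mode = c("simulation", "exome")) {
  mode <- match.arg(mode)
  stopifnot(all(p >= 0 & p <= 1))
  p < if (mode == "simulation") 0.05 else 2.5e-6
}

#' Association test of the fitted selection
#'
#' Collapses the variants selected by the fit into a virtual locus and runs
#' the burden test. An empty selection yields p = 1 (nothing to report).
#'
#' @param ds A `rare_dataset`.
#' @param fit An `hmrf_fit` (or an integer vector of selected sites).
#' @param mode Significance mode, see [declare_significance()].
#' @return One-row tibble: `n_selected`, carrier counts, `statistic`,
#'   `p_value`, `significant`, `threshold_used`, and the selected sites as a
#'   list column.
#' @export
assoc_test <- function(ds, fit, mode = c("simulation", "exome")) {
  mode <- match.arg(mode)
  selected <- if (inherits(fit, "hmrf_fit")) fit$selected_sites else
    as.integer(fit)
  threshold <- if (mode == "simulation") 0.05 else 2.5e-6
  if (!length(selected)) {
    return(tibble(n_selected = 0L, carriers_case = 0L, carriers_control = 0L,
                  statistic = 0, p_value = 1, significant = FALSE,
                  threshold_used = threshold, selected = list(integer(0))))
  }
  tab <- collapse_variants(ds, selected)
  bt <- burden_test(tab)
  tibble(n_selected = length(selected),
         carriers_case = tab["carrier", "case"],
         carriers_control = tab["carrier", "control"],
         statistic = bt$statistic, p_value = bt$p_value,
         significant = declare_significance(bt$p_value, mode),
         threshold_used = threshold, selected = list(selected))
}

#' Power and error rates over replicate datasets
#'
#' Aggregates replicate results with the study's definitions: power is the
#' fraction of significant datasets; the type-I error rate is the average
#' fraction of preset causal variants *not* selected; the type-II error rate
#' is the average fraction of preset neutral variants selected. (These
#' selection-level definitions are deliberate, not the usual hypothesis-test
#' rates.)
#'
#' @param results A tibble with columns `significant` (logical), `selected`
#'   (list of selected site indices) and `truth` (list of per-site 0/1 causal
#'   indicators).
#' @return One-row tibble: `n_datasets`, `power`, `type_i`, `type_ii`.
#' @export
evaluate_replicates <- function(results) {
  stopifnot(all(c("significant", "selected", "truth") %in% names(results)))
  per_ds <- purrr::map2_dfr(results$selected, results$truth,
                            function(sel, tr) {
    causal <- which(tr == 1)
    neutral <- which(tr == 0)
    tibble(
      type_i = if (length(causal)) mean(!causal %in% sel) else NA_real_,
      type_ii = if (length(neutral)) mean(neutral %in% sel) else NA_real_)
  })
  tibble(n_datasets = nrow(results),
         power = mean(results$significant),
         type_i = mean(per_ds$type_i, na.rm = TRUE),
         type_ii = mean(per_ds$type_ii, na.rm = TRUE))
}
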