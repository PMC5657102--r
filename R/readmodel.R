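#' Per-sample VAF estimates from read counts
#'
#' Converts tumour/normal supporting-read and depth matrices into variant
#' allelic frequency estimates `support / depth`. Entries with zero depth are
#' returned as `NA` and excluded from the per-site informative count.
#'
#' @param rc Read-count list with matrices `tumor_support`, `tumor_depth`,
#'   `normal_support`, `normal_depth` (as attached by [overlay_read_counts()]).
#' @return List with `tumor_vaf` and `normal_vaf` matrices and a per-site
#'   `n_informative` count (samples informative in both tissues).
#' @export
vaf_estimates <- function(rc) {
  stopifnot(all(c("tumor_support", "tumor_depth", "normal_support",
                  "normal_depth") %in% names(rc)))
  if (any(rc$tumor_support > rc$tumor_depth) ||
      any(rc$normal_support > rc$normal_depth))
    abort("Supporting reads exceed depth; corrupt read-count input.")
  tv <- rc$tumor_support / rc$tumor_depth
  nv <- rc$normal_support / rc$normal_depth
  tv[rc$tumor_depth == 0] <- NA_real_
  nv[rc$normal_depth == 0] <- NA_real_
  list(tumor_vaf = tv, normal_vaf = nv,
       n_informative = colSums(!is.na(tv) & !is.na(nv)))
}

#' Paired t statistic of tumour-vs-normal VAFs at a site
#'
#' The per-site statistic of the difference between the tumour VAF
#' \eqn{\theta_s} and the normal VAF \eqn{\rho_s}, computed as a paired t test
#' across samples. A zero-variance difference vector returns 0 when the mean
#' difference is zero and `sign(mean) * t_max` otherwise (the cap corresponds
#' to a p-value at machine precision).
#'
#' @param tumor_vafs,normal_vafs Paired per-sample VAFs (NAs dropped pairwise).
#' @param t_max Cap for degenerate zero-variance statistics.
#' @return The paired t statistic.
#' @export
site_t_statistic <- function(tumor_vafs, normal_vafs, t_max = 37.62) {
  stopifnot(length(tumor_vafs) == length(normal_vafs))
  d <- tumor_vafs - normal_vafs
  d <- d[!is.na(d)]
  if (length(d) < 2)
    abort("Fewer than 2 informative pairs; t statistic undefined.")
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(0)
    return(sign(mean(d)) * t_max)
  }
  t_val <- mean(d) / (s / sqrt(length(d)))
  max(min(t_val, t_max), -t_max)
}

#' Interaction weight between two sites from their t statistics
#'
#' \eqn{\omega_{s,s'} = 2 t_s t_{s'} / (t_s^2 + t_{s'}^2)}, a cosine-similarity
#' style kernel in \[-1, 1\]: 1 iff the statistics are equal and non-zero, -1
#' iff opposite, 0 when either vanishes. Defined as 0 when both are zero.
#'
#' @param t_a,t_b t statistics (vectorised).
#' @return Weights in \[-1, 1\].
#' @examples
#' interaction_weight(1, 3)
#' @export
interaction_weight <- function(t_a, t_b) {
  denom <- t_a^2 + t_b^2
  ifelse(denom == 0, 0, 2 * t_a * t_b / denom)
}

#' Per-site VAF statistics
#'
#' Computes, for each site, the paired t statistic of tumour-vs-normal VAF
#' difference and the mean VAFs. By default only carriers enter the test (the
#' VAF contrast is a property of samples that actually bear the variant); set
#' `carriers_only = FALSE` to use all informative samples. Somatic sites use
#' only tumour quantities: their normal VAF is treated as 0.
#'
#' @param ds A `rare_dataset` with read counts attached.
#' @param carriers_only Restrict the test to carrier samples?
#' @param t_max Degeneracy cap, see [site_t_statistic()].
#' @return A tibble with one row per site: `site`, `t_stat`,
#'   `tumor_vaf_mean`, `normal_vaf_mean`, `n_informative`. Sites with fewer
#'   than two informative pairs get `t_stat = 0` and are flagged
#'   `informative = FALSE`.
#' @export
site_stats <- function(ds, carriers_only = TRUE, t_max = 37.62) {
  stopifnot(inherits(ds, "rare_dataset"))
  if (is.null(ds$read_counts))
    abort("Dataset has no read counts; run `overlay_read_counts()` first.")
  v <- vaf_estimates(ds$read_counts)
  carrier <- carrier_matrix(ds)
  site_type <- ds$site_type %||% rep("germline", ncol(carrier))
  purrr::map_dfr(seq_len(ncol(carrier)), function(s) {
    tv <- v$tumor_vaf[, s]
    nv <- if (site_type[s] == "somatic") rep(0, length(tv)) else
      v$normal_vaf[, s]
    keep <- if (carriers_only) carrier[, s] == 1L else rep(TRUE, length(tv))
    tvs <- tv[keep]; nvs <- nv[keep]
    ok <- sum(!is.na(tvs - nvs))
    t_stat <- if (ok >= 2) site_t_statistic(tvs, nvs, t_max) else 0
    tibble(site = s, t_stat = t_stat,
           tumor_vaf_mean = mean(tvs, na.rm = TRUE),
           normal_vaf_mean = mean(nvs, na.rm = TRUE),
           n_informative = ok, informative = ok >= 2)
  })
}

#' Cluster somatic sites into sub-clones by mean carrier VAF
#'
#' A 1-D Gaussian mixture over per-site mean carrier VAFs, with the component
#' count chosen by BIC up to `k_max`. This is a deliberately simple stand-in
#' for full clonal-architecture reconstruction: interaction weights are only
#' computed within a sub-clone.
#'
#' @param vafs Per-site mean carrier VAFs (somatic sites).
#' @param k_max Maximum number of mixture components.
#' @return A tibble `site`, `vaf`, `cluster`, `cluster_mean_vaf`.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_subclones <- function(vafs, k_max = 5) {
  stopifnot(length(vafs) >= 1, k_max >= 1)
  vafs <- as.numeric(vafs)
  if (length(vafs) == 1 || length(unique(round(vafs, 8))) == 1) {
    return(tibble(site = seq_along(vafs), vaf = vafs, cluster = 1L,
                  cluster_mean_vaf = mean(vafs)))
  }
  gs <- seq_len(min(k_max, length(unique(vafs))))
  fit <- suppressWarnings(
    Mclust(vafs, G = gs, modelNames = "V", verbose = FALSE))
  if (is.null(fit))  # fall back to an equal-variance model on hard data
    fit <- suppressWarnings(
      Mclust(vafs, G = gs, modelNames = "E", verbose = FALSE))
  cl <- as.integer(fit$classification)
  means <- tapply(vafs, cl, mean)
  tibble(site = seq_along(vafs), vaf = vafs, cluster = cl,
         cluster_mean_vaf = as.numeric(means[as.character(cl)]))
}

#' Pairwise interaction weights within compatible intervals
#'
#' Builds the sparse symmetric weight map \eqn{\omega_{s,s'}} from per-site t
#' statistics: pairs must lie in the same compatible interval, and somatic
#' pairs additionally in the same sub-clone. Pairs where either site is
#' uninformative (no t statistic) are omitted; the fit treats such neighbours
#' with a unit prior coupling instead.
#'
#' @param stats Tibble from [site_stats()].
#' @param intervals Interval tibble from [find_compatible_intervals()]
#'   (`NULL` places all sites in one interval).
#' @param subclones Optional tibble from [cluster_subclones()] giving a
#'   `cluster` per site; applied to somatic sites.
#' @param site_type Optional per-site `"germline"`/`"somatic"` vector.
#' @return A tibble `s1`, `s2` (1-based, `s1 < s2`), `omega`.
#' @export
interaction_weights <- function(stats, intervals = NULL, subclones = NULL,
                                site_type = NULL) {
  m <- nrow(stats)
  iv <- site_interval_index(intervals, m)
  cl <- if (is.null(subclones)) rep(1L, m) else subclones$cluster
  st <- site_type %||% rep("germline", m)
  info <- which(stats$informative & stats$t_stat != 0)
  if (length(info) < 2)
    return(tibble(s1 = integer(), s2 = integer(), omega = numeric()))
  pairs <- t(utils::combn(info, 2))
  keep <- iv[pairs[, 1]] == iv[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]
  omega <- interaction_weight(stats$t_stat[pairs[, 1]],
                              stats$t_stat[pairs[, 2]])
  # somatic pairs interact only within a sub-clone
  cross_clone <- st[pairs[, 1]] == "somatic" & st[pairs[, 2]] == "somatic" &
    cl[pairs[, 1]] != cl[pairs[, 2]]
  omega[cross_clone] <- 0
  tibble(s1 = pairs[, 1], s2 = pairs[, 2], omega = omega)
}

# 1-based interval index per site from a 0-based half-open interval tibble.
site_interval_index <- function(intervals, m) {
  if (is.null(intervals)) return(rep(1L, m))
  idx <- integer(m)
  for (i in seq_len(nrow(intervals)))
    idx[(intervals$start[i] + 1L):intervals$end[i]] <- i
  idx
}
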