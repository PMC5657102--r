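#' Simulation configuration for fixed-number case/control datasets
#'
#' Bundles the parameters of the fixed-number simulation strategy: `n_causal`
#' of `n_sites` variants are preset as causal, control-population minor allele
#' frequencies follow Wright's distribution, and the causal case-population
#' frequencies are driven by the marginal population attributable risk (PAR)
#' `delta = group_par / n_causal` through the relative risk.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param n_sites Number of variant sites M.
#' @param n_causal Number of preset causal variants C (`<= n_sites`).
#' @param group_par Group population attributable risk, in (0, 1); the
#'   simulation study varies it over 0.02-0.05.
#' @param sigma,beta_site,beta_repair Wright's distribution parameters
#'   (selection coefficient, causal-mutation and repair probabilities).
#' @param maf_upper Optional truncation of the control MAF distribution.
#' @param coding `"diploid"` draws 0/1/2 allele counts per sample;
#'   `"carrier"` draws 0/1 carrier indicators. The selection model always
#'   collapses to carrier status.
#' @param seed Optional integer seed recorded in the config.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(group_par = 0.05, n_causal = 50)
#' @export
sim_config <- function(n_cases = 1000, n_controls = 1000, n_sites = 100,
                       n_causal = 50, group_par = 0.02, sigma = 12,
                       beta_site = 0.001, beta_repair = 0.00033,
                       maf_upper = NULL, coding = c("diploid", "carrier"),
                       seed = NULL) {
  coding <- match.arg(coding)
  stopifnot(n_cases >= 1, n_controls >= 1, n_sites >= 1)
  if (n_causal > n_sites) abort("`n_causal` must not exceed `n_sites`.")
  if (group_par < 0 || group_par >= 1)
    abort("`group_par` must lie in [0, 1).")
  check_wright_params(sigma, beta_site, beta_repair)
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_sites = as.integer(n_sites), n_causal = as.integer(n_causal),
         group_par = group_par, sigma = sigma, beta_site = beta_site,
         beta_repair = beta_repair, maf_upper = maf_upper, coding = coding,
         seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_cases, " cases / ", x$n_controls, " controls, ",
      x$n_sites, " sites (", x$n_causal, " causal), group PAR ", x$group_par,
      "\n  Wright(sigma = ", x$sigma, ", beta_i = ", x$beta_site,
      ", beta_L = ", x$beta_repair, "), coding ", x$coding, "\n", sep = "")
  invisible(x)
}

#' Relative risk of a causal variant from its marginal PAR
#'
#' \eqn{RR = \delta / ((1-\delta)\rho) + 1}, where `delta` is the marginal
#' population attributable risk (group PAR split equally over the causal
#' variants) and `rho` the control-population MAF.
#'
#' @param delta Marginal PAR, in \[0, 1).
#' @param rho Control MAF, in (0, 1).
#' @return Relative risk, `>= 1`; equals 1 iff `delta == 0`.
#' @examples
#' relative_risk(0.001, 0.01)
#' @export
relative_risk <- function(delta, rho) {
  if (any(delta < 0 | delta >= 1)) abort("`delta` must lie in [0, 1).")
  if (any(rho <= 0 | rho >= 1))
    abort("`rho` must lie in (0, 1); a zero MAF has no defined relative risk.")
  delta / ((1 - delta) * rho) + 1
}

#' Case-population MAF implied by a relative risk
#'
#' \eqn{\theta = RR\,\rho / ((RR - 1)\rho + 1)}: the frequency a variant with
#' control MAF `rho` attains among cases under relative risk `rr`.
#'
#' @param rr Relative risk (`>= 1`).
#' @param rho Control MAF in (0, 1).
#' @return Case MAF in (0, 1); equals `rho` when `rr == 1`.
#' @examples
#' case_maf(relative_risk(0.0004, 0.005), 0.005)
#' @export
case_maf <- function(rr, rho) {
  if (any(rr < 1)) abort("`rr` must be >= 1.")
  if (any(rho <= 0 | rho >= 1)) abort("`rho` must lie in (0, 1).")
  rr * rho / ((rr - 1) * rho + 1)
}

new_rare_dataset <- function(genotypes, labels, causal_truth, control_mafs,
                             case_mafs, read_counts = NULL, site_type = NULL,
                             coding = "diploid") {
  stopifnot(nrow(genotypes) == length(labels),
            ncol(genotypes) == length(causal_truth))
  structure(
    list(genotypes = genotypes, labels = labels,
         causal_truth = as.integer(causal_truth),
         control_mafs = control_mafs, case_mafs = case_mafs,
         read_counts = read_counts, site_type = site_type, coding = coding),
    class = "rare_dataset")
}

#' @export
print.rare_dataset <- function(x, ...) {
  cat("<rare_dataset> ", nrow(x$genotypes), " samples (",
      sum(x$labels == "case"), " cases) x ", ncol(x$genotypes), " sites; ",
      sum(x$causal_truth), " causal; coding ", x$coding,
      if (!is.null(x$read_counts)) "; read counts attached" else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.rare_dataset <- function(x, ...) {
  g <- as_tibble(as.data.frame(x$genotypes))
  dplyr::bind_cols(tibble(sample = rownames(x$genotypes), label = x$labels), g)
}

#' Carrier indicator matrix of a dataset
#'
#' Collapses genotypes to carrier status: any non-reference allele makes a
#' sample a carrier at that site.
#'
#' @param ds A `rare_dataset`.
#' @return Integer 0/1 matrix, samples by sites.
#' @export
carrier_matrix <- function(ds) {
  stopifnot(inherits(ds, "rare_dataset"))
  m <- (ds$genotypes >= 1L) * 1L
  dimnames(m) <- dimnames(ds$genotypes)
  m
}

#' Generate a fixed-number case/control dataset
#'
#' Draws control MAFs from Wright's distribution, presets `n_causal` random
#' sites as causal (recorded in `causal_truth`), lifts their case MAFs through
#' [relative_risk()] and [case_maf()] with the marginal PAR
#' `group_par / n_causal`, and samples every genotype independently (the
#' fixed-number strategy assumes no linkage disequilibrium among rare
#' variants).
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (overrides `cfg$seed`).
#' @return A `rare_dataset` with cases stacked before controls.
#' @examples
#' ds <- generate_dataset(sim_config(n_cases = 50, n_controls = 50), seed = 1)
#' ds
#' @export
generate_dataset <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- seed %||% cfg$seed
  with_seed(seed, {
    m <- cfg$n_sites
    rho <- sample_wright_maf(m, cfg$sigma, cfg$beta_site, cfg$beta_repair,
                             cfg$maf_upper)
    causal <- sort(sample.int(m, cfg$n_causal))
    delta <- if (cfg$n_causal > 0) cfg$group_par / cfg$n_causal else 0
    theta <- rho
    if (delta > 0 && cfg$n_causal > 0)
      theta[causal] <- case_maf(relative_risk(delta, rho[causal]), rho[causal])
    ploidy <- if (cfg$coding == "diploid") 2L else 1L
    n <- cfg$n_cases + cfg$n_controls
    geno <- matrix(0L, n, m)
    for (s in seq_len(m)) {
      geno[, s] <- c(rbinom(cfg$n_cases, ploidy, theta[s]),
                     rbinom(cfg$n_controls, ploidy, rho[s]))
    }
    labels <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
    rownames(geno) <- sprintf("S%04d", seq_len(n))
    colnames(geno) <- sprintf("site%03d", seq_len(m))
    truth <- integer(m); truth[causal] <- 1L
    new_rare_dataset(geno, labels, truth, rho, theta, coding = cfg$coding)
  })
}

#' Generate a null-model dataset
#'
#' Every genotype entry is an independent Bernoulli(`mut_prob`) carrier
#' indicator and every sample is a case or a control with equal probability;
#' no site is causal. Used to measure the dataset-level false-report rate of
#' the full pipeline.
#'
#' @param n_samples,n_sites Dataset dimensions.
#' @param mut_prob Per-entry mutation probability.
#' @param seed Optional integer seed.
#' @return A `rare_dataset` with `causal_truth` all zero.
#' @examples
#' generate_null_dataset(100, 20, seed = 1)
#' @export
generate_null_dataset <- function(n_samples = 1000, n_sites = 100,
                                  mut_prob = 0.005, seed = NULL) {
  if (mut_prob < 0 || mut_prob >= 1) abort("`mut_prob` must lie in [0, 1).")
  with_seed(seed, {
    geno <- matrix(rbinom(n_samples * n_sites, 1L, mut_prob),
                   n_samples, n_sites)
    labels <- ifelse(runif(n_samples) < 0.5, "case", "control")
    rownames(geno) <- sprintf("S%04d", seq_len(n_samples))
    colnames(geno) <- sprintf("site%03d", seq_len(n_sites))
    new_rare_dataset(geno, labels, integer(n_sites),
                     rep(mut_prob, n_sites), rep(mut_prob, n_sites),
                     coding = "carrier")
  })
}

#' Overlay synthetic tumour/normal read counts on a dataset
#'
#' Simulation datasets carry genotypes only; the VAF-based interaction weights
#' need read counts. This overlay draws per-sample per-site depths from a
#' shifted Poisson (minimum 1) and supporting reads from binomials whose
#' success probability reflects the sample's carrier status: germline carriers
#' are heterozygous in both tissues (VAF `germline_vaf`), somatic carriers
#' carry the variant only in the tumour at a (sub)clonal fraction, and
#' non-carriers yield sequencing-error support at `error_rate`.
#'
#' @param ds A `rare_dataset`.
#' @param depth_mean Mean sequencing depth (both tissues).
#' @param error_rate Per-read error support probability for non-carriers.
#' @param site_type `"germline"` or `"somatic"`, length 1 or one per site.
#' @param germline_vaf Heterozygous VAF used in both tissues at germline sites.
#' @param tumor_vaf Tumour VAF of somatic carriers; a vector describes
#'   sub-clones and each somatic site is assigned one clone fraction at random.
#' @param seed Optional integer seed.
#' @return The dataset with a `read_counts` list of four matrices
#'   (`tumor_support`, `tumor_depth`, `normal_support`, `normal_depth`) and a
#'   per-site `site_type` vector.
#' @export
overlay_read_counts <- function(ds, depth_mean = 60, error_rate = 0.001,
                                site_type = "somatic", germline_vaf = 0.5,
                                tumor_vaf = 0.4, seed = NULL) {
  stopifnot(inherits(ds, "rare_dataset"), depth_mean > 0)
  n <- nrow(ds$genotypes); m <- ncol(ds$genotypes)
  site_type <- rep(site_type, length.out = m)
  with_seed(seed, {
    carrier <- carrier_matrix(ds)
    clone_vaf <- rep(tumor_vaf, length.out = max(length(tumor_vaf), 1))
    site_clone <- sample(clone_vaf, m, replace = TRUE)
    vaf_t <- matrix(error_rate, n, m)
    vaf_n <- matrix(error_rate, n, m)
    for (s in seq_len(m)) {
      idx <- carrier[, s] == 1L
      if (site_type[s] == "germline") {
        vaf_t[idx, s] <- germline_vaf
        vaf_n[idx, s] <- germline_vaf
      } else {
        vaf_t[idx, s] <- site_clone[s]
      }
    }
    td <- matrix(pmax(rpois(n * m, depth_mean), 1L), n, m)
    nd <- matrix(pmax(rpois(n * m, depth_mean), 1L), n, m)
    ts <- matrix(rbinom(n * m, as.vector(td), as.vector(vaf_t)), n, m)
    ns <- matrix(rbinom(n * m, as.vector(nd), as.vector(vaf_n)), n, m)
    dimnames(td) <- dimnames(nd) <- dimnames(ts) <- dimnames(ns) <-
      dimnames(ds$genotypes)
    ds$read_counts <- list(tumor_support = ts, tumor_depth = td,
                           normal_support = ns, normal_depth = nd)
    ds$site_type <- site_type
    attr(ds$read_counts, "clone_vaf") <- site_clone
    ds
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
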