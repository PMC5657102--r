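#' Wright's distribution for rare-variant minor allele frequencies
#'
#' Unnormalised density \eqn{f(\rho) \propto \rho^{\beta_i-1} (1-\rho)^{\beta_L-1}
#' e^{\sigma - \rho\sigma}} on (0, 1), where \eqn{\sigma} is the selection
#' coefficient, \eqn{\beta_i} the probability of mutating a neutral variant to
#' a causal one and \eqn{\beta_L} the probability of repairing a causal variant
#' to a neutral one. At the default parameters the exponents are tiny, so the
#' density carries integrable spikes at both endpoints and almost all mass sits
#' at extremely small frequencies.
#'
#' @param rho Frequencies in (0, 1).
#' @param sigma Selection coefficient (> 0).
#' @param beta_site Mutation probability \eqn{\beta_i} (in (0, 1)).
#' @param beta_repair Repair probability \eqn{\beta_L} (in (0, 1)).
#' @param log Return the log density?
#' @return Unnormalised density values.
#' @export
dwright <- function(rho, sigma = 12, beta_site = 0.001, beta_repair = 0.00033,
                    log = FALSE) {
  check_wright_params(sigma, beta_site, beta_repair)
  ld <- (beta_site - 1) * base::log(rho) + (beta_repair - 1) * log1p(-rho) -
    sigma * rho
  ld[rho <= 0 | rho >= 1] <- -Inf
  if (log) ld else exp(ld)
}

check_wright_params <- function(sigma, beta_site, beta_repair) {
  if (!is.finite(sigma) || sigma <= 0)
    abort("`sigma` must be a positive number.")
  if (!is.finite(beta_site) || beta_site <= 0 || beta_site > 1 ||
      !is.finite(beta_repair) || beta_repair <= 0 || beta_repair > 1)
    abort("`beta_site` and `beta_repair` must lie in (0, 1]; the normalising constant is not finite otherwise.")
  invisible(TRUE)
}

# Three-piece decomposition of the Wright density. The endpoint spikes
# rho^(b_i - 1) and (1 - rho)^(b_L - 1) are handled analytically on
# (0, eps] and [1 - eps, 1); the smooth middle is tabulated on a log grid.
# All masses drop the constant factor e^sigma, which cancels on normalising.
wright_pieces <- function(sigma, beta_site, beta_repair, eps = 1e-6,
                          n_grid = 2e4) {
  f <- function(r) exp((beta_site - 1) * log(r) + (beta_repair - 1) * log1p(-r) -
                         sigma * r)
  z_low <- eps^beta_site / beta_site            # integrand ~ r^(b_i - 1) near 0
  z_top <- exp(-sigma) * eps^beta_repair / beta_repair
  grid <- exp(seq(log(eps), log(1 - eps), length.out = n_grid + 1))
  dens_log <- f(grid) * grid                    # density of log(rho)
  steps <- diff(log(grid))
  cell <- (dens_log[-1] + dens_log[-(n_grid + 1)]) / 2 * steps
  z_mid <- sum(cell)
  cdf_mid <- cumsum(cell) / z_mid
  list(eps = eps, grid = grid, cdf_mid = cdf_mid,
       z = c(low = z_low, mid = z_mid, top = z_top),
       sigma = sigma, beta_site = beta_site, beta_repair = beta_repair)
}

# Numerically normalised CDF built from the same three pieces; used both by
# the truncation logic and as a target for distributional checks.
wright_cdf <- function(q, sigma = 12, beta_site = 0.001, beta_repair = 0.00033,
                       pieces = NULL) {
  if (is.null(pieces)) pieces <- wright_pieces(sigma, beta_site, beta_repair)
  ztot <- sum(pieces$z)
  vapply(q, function(x) {
    if (x <= 0) return(0)
    if (x >= 1) return(1)
    if (x <= pieces$eps) return(x^pieces$beta_site / pieces$beta_site / ztot)
    if (x >= 1 - pieces$eps) {
      tail_mass <- exp(-pieces$sigma) * (1 - x)^pieces$beta_repair /
        pieces$beta_repair
      return(1 - tail_mass / ztot)
    }
    i <- findInterval(x, pieces$grid)
    frac <- if (i >= length(pieces$cdf_mid)) 1 else pieces$cdf_mid[i]
    (pieces$z[["low"]] + frac * pieces$z[["mid"]]) / ztot
  }, numeric(1))
}

#' Sample minor allele frequencies from Wright's distribution
#'
#' Draws i.i.d. frequencies from the normalised Wright density via a
#' three-piece inverse-CDF scheme: the \eqn{\rho^{\beta_i-1}} spike at 0 and
#' the \eqn{(1-\rho)^{\beta_L-1}} spike at 1 are inverted analytically, and the
#' smooth middle is inverted from a tabulated CDF on a log-spaced grid
#' (rejection sampling is hopeless at \eqn{\beta_i = 0.001}, where the
#' acceptance region is a sliver at 0). Draws that underflow double precision
#' are clamped to `1e-300` so every frequency stays strictly positive.
#'
#' @param n Number of draws (>= 0).
#' @inheritParams dwright
#' @param maf_upper Optional truncation: draws are conditioned on
#'   `rho <= maf_upper`. `NULL` (default) leaves the distribution untruncated.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` frequencies in (0, 1).
#' @examples
#' sample_wright_maf(5, seed = 1)
#' @export
sample_wright_maf <- function(n, sigma = 12, beta_site = 0.001,
                              beta_repair = 0.00033, maf_upper = NULL,
                              seed = NULL) {
  check_wright_params(sigma, beta_site, beta_repair)
  if (n == 0) return(numeric(0))
  stopifnot(n >= 1)
  if (!is.null(maf_upper) &&
      (!is.finite(maf_upper) || maf_upper <= 0 || maf_upper > 1))
    abort("`maf_upper` must lie in (0, 1].")
  pieces <- wright_pieces(sigma, beta_site, beta_repair)
  with_seed(seed, {
    # Inverse-CDF: map uniforms through the truncated three-piece CDF.
    cap <- if (is.null(maf_upper)) 1 else maf_upper
    pcap <- if (cap >= 1) 1 else
      wright_cdf(cap, pieces = pieces)
    u <- runif(n) * pcap
    ztot <- sum(pieces$z)
    p_low <- pieces$z[["low"]] / ztot
    p_mid <- pieces$z[["mid"]] / ztot
    out <- numeric(n)
    lo <- u < p_low
    hi <- u >= p_low + p_mid
    mid <- !lo & !hi
    if (any(lo)) {
      # CDF on (0, eps] is (rho/eps)^beta_i * p_low
      out[lo] <- pmax(exp(log(pieces$eps) + log(u[lo] / p_low) / beta_site),
                      1e-300)
    }
    if (any(mid)) {
      frac <- (u[mid] - p_low) / p_mid
      out[mid] <- pieces$grid[findInterval(frac, pieces$cdf_mid) + 1L]
    }
    if (any(hi)) {
      tail_mass <- pmax(1 - u[hi], 1e-300) * ztot
      out[hi] <- 1 - pmax(
        exp((log(tail_mass) + pieces$sigma + log(beta_repair)) / beta_repair),
        1e-300)
    }
    pmin(out, if (is.null(maf_upper)) 1 - 1e-16 else maf_upper)
  })
}
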