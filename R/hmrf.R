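#' The f relaxation function
#'
#' \eqn{f(x) = (1 - e^{-x}) / n}: the saturating relaxation used throughout
#' the field transition potentials. `f(0) = 0`, increasing in `x`, with limit
#' `1/n`.
#'
#' @param x Argument (any real).
#' @param n Sample count divisor (`>= 1`).
#' @return `(1 - exp(-x)) / n`.
#' @examples
#' f_func(1, 4)
#' @export
f_func <- function(x, n) {
  stopifnot(n >= 1)
  (1 - exp(-x)) / n
}

#' Hidden-state transition potential between two sites
#'
#' Unnormalised potential
#' \eqn{P(H_s | H_{s'}, \theta) \propto \exp\{ n [\mu + (1-\mu)
#' f(-\theta d + I e^{-\theta d})] \}}, where `mu` is the mutation rate by
#' which a variant occurs independently, `theta_region` the deleterious-region
#' likelihood parameter, `d` the genetic distance between the sites and the
#' indicator `I = 1` when the states agree. The potential must be normalised
#' over the state space before use in recursions.
#'
#' @param mu Mutation rate in (0, 1\].
#' @param theta_region Region likelihood parameter (> 0).
#' @param d Genetic distance (>= 0).
#' @param same_state Do the two hidden states agree?
#' @param n Number of samples.
#' @return The unnormalised potential (positive scalar).
#' @export
trans_H <- function(mu, theta_region, d, same_state, n) {
  stopifnot(mu >= 0, mu <= 1, theta_region >= 0, d >= 0, n >= 1)
  i_ss <- as.numeric(same_state)
  x <- -theta_region * d + i_ss * exp(-theta_region * d)
  exp(n * (mu + (1 - mu) * f_func(x, n)))
}

#' Silent-state transition probabilities
#'
#' The duplicate channel \eqn{P(J_i^s | R_s) = f(-\theta d) + e^{-\theta d}}
#' and the permutation channel
#' \eqn{P(J_{i,\cdot}^s | R_s) = f(-\theta d) / (N - 1)}, clipped to \[0, 1\]
#' after evaluation (the permutation channel is non-positive whenever
#' \eqn{\theta d > 0} and clips to zero). The duplicate channel decays from 1
#' at `d = 0` towards 0 as \eqn{\theta d} grows.
#'
#' @inheritParams trans_H
#' @return Named vector `c(duplicate = , permute = )`.
#' @export
trans_J <- function(theta_region, d, n) {
  stopifnot(theta_region >= 0, d >= 0, n >= 2)
  dup <- f_func(-theta_region * d, n) + exp(-theta_region * d)
  perm <- f_func(-theta_region * d, n) / (n - 1)
  c(duplicate = min(max(dup, 0), 1), permute = min(max(perm, 0), 1))
}

#' Normalised region-chain transition kernel
#'
#' The working Markov kernel of the region chain: a state persists with the
#' duplicate-channel weight \eqn{e^{-\theta d}} and is otherwise redrawn
#' uniformly over the `n_states` region states, giving
#' \eqn{P(\text{stay}) = e^{-\theta d} + (1 - e^{-\theta d})/J}. This is the
#' normalised reconstruction of the silent-state channels of [trans_J()].
#'
#' @param theta_region Region persistence parameter (> 0).
#' @param d Genetic distance between adjacent sites.
#' @param n_states Number of region states (default 2).
#' @return A `n_states` x `n_states` stochastic matrix.
#' @export
region_transition <- function(theta_region, d = 1, n_states = 2) {
  persist <- exp(-theta_region * d)
  stay <- persist + (1 - persist) / n_states
  switch_p <- (1 - persist) / n_states
  mat <- matrix(switch_p, n_states, n_states)
  diag(mat) <- stay
  mat
}

#' Elevated-region potential at a site
#'
#' Unnormalised potential for \eqn{R_s} elevated:
#' \eqn{\exp\{\tau B(P^e_s, P^b_s) + \nu \sum_{s'} \omega_{s,s'} R_{s'}\}},
#' where the solo term `b_val` is the Bernoulli log-odds
#' \eqn{\log(P^e/P^b)} (or the difference `P^e - P^b`) and each neighbour
#' contributes its current elevated posterior weighted by the interaction
#' weight. Neighbours must lie in the site's compatible interval.
#'
#' @param b_val Solo-effect term \eqn{B(P^e_s, P^b_s)}.
#' @param neighbor_r Elevated posteriors \eqn{P(R_{s'} | X)} of neighbours.
#' @param omega Interaction weights, recycled to the neighbour count.
#' @param tau,nu Solo and interaction weights, `tau + nu = 1`.
#' @return The unnormalised potential.
#' @examples
#' region_potential(log(0.6 / 0.4), 1, 1)  # exp(0.5 log 1.5 + 0.5)
#' @export
region_potential <- function(b_val, neighbor_r = numeric(0), omega = 1,
                             tau = 0.5, nu = 0.5) {
  if (abs(tau + nu - 1) > 1e-8) abort("`tau + nu` must equal 1.")
  omega <- rep(omega, length.out = length(neighbor_r))
  exp(tau * b_val + nu * sum(omega * neighbor_r))
}

#' Scaled forward-backward recursion for the region chain
#'
#' Runs the scaled forward and backward recursions over a chain whose state
#' space interleaves region flags with the collapsed hidden-genotype
#' representative: even-numbered states (1st, 3rd, ... columns) carry the
#' background weight \eqn{P^b_s}, odd-numbered states the elevated weight
#' \eqn{P^e_s} (the `mode(j, 2)` parity rule). With the scaling used here
#' \eqn{\sum_i \alpha_s(i) \beta_s(i) = 1} at every site, and the per-site
#' posterior is exactly `alpha * beta`.
#'
#' @param emissions M x J matrix of per-site state likelihoods
#'   \eqn{P(R_s | X)} (linear scale; may be unnormalised).
#' @param transition J x J transition matrix, e.g. [region_transition()].
#' @param p_e Optional per-site elevated prior \eqn{P^e_s}; odd states are
#'   weighted by `p_e`, even states by `1 - p_e`.
#' @param prior Initial state distribution (default uniform).
#' @return A `trellis` object: `alpha`, `beta`, `posterior` (M x J),
#'   `scaling`, `loglik`.
#' @export
forward_backward_R <- function(emissions, transition, p_e = NULL,
                               prior = NULL) {
  emissions <- as.matrix(emissions)
  m <- nrow(emissions); j <- ncol(emissions)
  stopifnot(m >= 1, nrow(transition) == j, ncol(transition) == j)
  if (!is.null(p_e)) {
    flag <- (seq_len(j) - 1L) %% 2L  # 0 = background, 1 = elevated
    wts <- outer(p_e, flag) + outer(1 - p_e, 1 - flag)
    emissions <- emissions * wts
  }
  prior <- prior %||% rep(1 / j, j)
  alpha <- matrix(0, m, j); scaling <- numeric(m)
  alpha[1, ] <- prior * emissions[1, ]
  scaling[1] <- sum(alpha[1, ])
  if (scaling[1] <= 0 || !is.finite(scaling[1]))
    abort("Forward recursion underflow: degenerate emissions.")
  alpha[1, ] <- alpha[1, ] / scaling[1]
  if (m > 1) for (s in 2:m) {
    alpha[s, ] <- as.vector(alpha[s - 1, ] %*% transition) * emissions[s, ]
    scaling[s] <- sum(alpha[s, ])
    if (scaling[s] <= 0 || !is.finite(scaling[s]))
      abort("Forward recursion underflow: degenerate emissions.")
    alpha[s, ] <- alpha[s, ] / scaling[s]
  }
  beta <- matrix(0, m, j)
  beta[m, ] <- 1
  if (m > 1) for (s in (m - 1):1) {
    beta[s, ] <- as.vector(transition %*% (beta[s + 1, ] * emissions[s + 1, ])) /
      scaling[s + 1]
  }
  posterior <- alpha * beta
  structure(list(alpha = alpha, beta = beta, posterior = posterior,
                 scaling = scaling, loglik = sum(log(scaling)),
                 emissions = emissions, transition = transition),
            class = "trellis")
}

#' Pairwise posterior tables from a trellis
#'
#' \eqn{\xi_R(s, i, j) = \alpha_s(i) T(i,j) P(R_{s+1}|X)(j) \beta_{s+1}(j) /
#' \text{norm}}: the joint posterior of adjacent region states, one normalised
#' J x J slice per adjacent pair.
#'
#' @param tables A `trellis` from [forward_backward_R()].
#' @return Array of dimension (M - 1) x J x J; each slice sums to 1.
#' @export
xi_pairwise <- function(tables) {
  stopifnot(inherits(tables, "trellis"))
  m <- nrow(tables$alpha); j <- ncol(tables$alpha)
  if (m < 2) return(array(numeric(0), dim = c(0, j, j)))
  xi <- array(0, dim = c(m - 1, j, j))
  for (s in seq_len(m - 1)) {
    slice <- (tables$alpha[s, ] %o%
                (tables$emissions[s + 1, ] * tables$beta[s + 1, ])) *
      tables$transition / tables$scaling[s + 1]
    xi[s, , ] <- slice / sum(slice)
  }
  xi
}

#' EM update of the mutation rate
#'
#' \eqn{\mu_{r+1} = \sum_{i,s} I(H_s \neq G_{i,s}) P(H_s|G) /
#' \sum_{i,s} I(G_{i,s} > 0) P(H_s|G)}: the posterior-weighted fraction of
#' carrier mass that disagrees with the hidden consensus, i.e. the share of
#' observed carrier entries attributable to independent mutation noise.
#'
#' @param h_hat Hidden consensus genotype matrix (same shape as `genotypes`).
#' @param genotypes Observed carrier/genotype matrix (samples x sites).
#' @param posteriors Per-site posterior weights \eqn{P(H_s | G)} (length M),
#'   or a full samples x sites weight matrix.
#' @return Updated `mu`, clipped to \[0, 1\].
#' @export
em_update_mu <- function(h_hat, genotypes, posteriors) {
  stopifnot(all(dim(h_hat) == dim(genotypes)))
  w <- if (is.matrix(posteriors)) posteriors
  else matrix(posteriors, nrow(genotypes), ncol(genotypes), byrow = TRUE)
  num <- sum((h_hat != genotypes) * w)
  den <- sum((genotypes > 0) * w)
  if (den <= 0)
    abort("All-reference genotype matrix: mutation-rate update undefined.")
  min(max(num / den, 0), 1)
}

#' EM update of the region persistence parameter
#'
#' Maximises the expected complete-data transition log-likelihood
#' \eqn{\sum_s q_s \log P_{\text{stay}}(\theta, d_s) + (1 - q_s)
#' \log(1 - P_{\text{stay}}(\theta, d_s))}, where \eqn{q_s} is the posterior
#' probability (from \eqn{\xi_R}) that adjacent sites share a region flag.
#' One-dimensional numeric maximisation over `bounds`, with a grid fallback
#' that guards against non-unimodal objectives.
#'
#' @param xi Array from [xi_pairwise()] (or a list of arrays, one per
#'   interval segment).
#' @param distances Adjacent-pair distances, recycled.
#' @param bounds Search interval for `theta`.
#' @param n_states Region-state count of the kernel.
#' @param grid_n Size of the fallback grid.
#' @return The maximising `theta`.
#' @export
em_update_theta <- function(xi, distances = 1, bounds = c(0.05, 2),
                            n_states = 2, grid_n = 64) {
  xis <- if (is.list(xi)) xi else list(xi)
  q_same <- unlist(purrr::map(xis, function(x) {
    if (!length(x)) return(numeric(0))
    flag <- (seq_len(dim(x)[2]) - 1L) %% 2L
    same <- outer(flag, flag, "==")
    apply(x, 1, function(sl) sum(sl[same]))
  }))
  if (!length(q_same)) {
    warn("Degenerate single-site input; returning the lower bound for theta.")
    return(bounds[1])
  }
  d <- rep(distances, length.out = length(q_same))
  q_same <- pmin(pmax(q_same, 1e-12), 1 - 1e-12)
  obj <- function(th) {
    persist <- exp(-th * d)
    stay <- persist + (1 - persist) / n_states
    sum(q_same * log(stay) + (1 - q_same) * log1p(-stay))
  }
  opt <- optimize(obj, bounds, maximum = TRUE)
  grid <- seq(bounds[1], bounds[2], length.out = grid_n)
  gv <- vapply(grid, obj, numeric(1))
  if (max(gv) > opt$objective + 1e-9) grid[which.max(gv)] else opt$maximum
}

#' EM update of the background transition probability
#'
#' \eqn{(P^b_s)_{r+1} = \xi_R(s, 0, 0) / \{(1/N)(1 + (N-1)e^{-\theta
#' d_{s,s'}})\}}, clipped to `(eps, 1 - eps)`; \eqn{P^e_s} is set to the
#' complement. The last site reuses the final adjacent pair.
#'
#' @param xi Array from [xi_pairwise()].
#' @param theta_region,distances Kernel parameters of the denominator.
#' @param n Sample count N.
#' @param eps Clipping margin.
#' @return List with per-site `p_b` and `p_e` (lengths M).
#' @export
em_update_pb <- function(xi, theta_region, distances = 1, n = 2,
                         eps = 1e-3) {
  m1 <- dim(xi)[1]
  stopifnot(m1 >= 1)
  d <- rep(distances, length.out = m1)
  x00 <- xi[, 1, 1]
  den <- (1 / n) * (1 + (n - 1) * exp(-theta_region * d))
  p_b <- pmin(pmax(x00 / den, eps), 1 - eps)
  p_b <- c(p_b, p_b[m1])
  list(p_b = p_b, p_e = 1 - p_b)
}

# ---- the working fit ------------------------------------------------------

#' Configuration of the HMRF fit
#'
#' Tunable parameters of the hidden Markov random field selection model. The
#' defaults are the package's calibrated operating point; see the methods
#' vignette for the reasoning behind each value.
#'
#' @param tau,nu Solo-effect and interaction weights (`tau + nu = 1`).
#' @param coupling Interaction field strength multiplying each neighbour's
#'   weighted elevation in the causal-status update.
#' @param window Neighbourhood half-width (sites), intersected with the
#'   four-gamete interval.
#' @param rare_max Carrier-frequency candidacy ceiling: sites with observed
#'   carrier frequency above this are never candidate causal variants (the
#'   usual rare-variant MAF filter).
#' @param m_floor Robustness floor on the solo evidence term in the
#'   causal-status update (truncated potential).
#' @param theta0,theta_bounds Initial value and search range of the region
#'   persistence parameter.
#' @param mu0 Initial mutation rate (re-estimated each iteration).
#' @param pe0 Initial per-site elevated probability.
#' @param b_form Solo region potential: Bernoulli log-odds `log(pe/pb)`
#'   (default) or the difference `pe - pb`.
#' @param tol Convergence threshold on parameter change.
#' @param max_iter Maximum EM iterations.
#' @param max_sweeps Maximum ICM sweeps per update.
#' @param gate_mult Model-selection gate: the elevated component must improve
#'   2 log-likelihood over the single-component null fit by more than
#'   `gate_mult * log(M)` for any site to be selected.
#' @param pe_eps Clipping margin for `p_e`.
#' @return An object of class `hmrf_config`.
#' @export
hmrf_config <- function(tau = 0.5, nu = 0.5, coupling = 1.2, window = 3,
                        rare_max = 0.02, m_floor = -1.25, theta0 = 1,
                        theta_bounds = c(0.05, 2), mu0 = 0.01, pe0 = 0.5,
                        b_form = c("logodds", "difference"), tol = 1e-4,
                        max_iter = 60, max_sweeps = 20, gate_mult = 3,
                        pe_eps = 0.01) {
  if (abs(tau + nu - 1) > 1e-8) abort("`tau + nu` must equal 1.")
  structure(list(tau = tau, nu = nu, coupling = coupling, window = window,
                 rare_max = rare_max, m_floor = m_floor, theta0 = theta0,
                 theta_bounds = theta_bounds, mu0 = mu0, pe0 = pe0,
                 b_form = match.arg(b_form), tol = tol, max_iter = max_iter,
                 max_sweeps = max_sweeps, gate_mult = gate_mult,
                 pe_eps = pe_eps),
            class = "hmrf_config")
}

# Per-site elevated/background log evidence given component parameters.
site_evidence <- function(a, k, n, w0, rate_bg, rate_e, w1, cand) {
  lme <- dpois(k, n * rate_e, log = TRUE) + dbinom(a, k, w1, log = TRUE)
  lmb <- dpois(k, n * rate_bg, log = TRUE) + dbinom(a, k, w0, log = TRUE)
  lme[!cand] <- lmb[!cand] - 50  # common variants are background by fiat
  list(lme = lme, lmb = lmb)
}

# Neighbour structure: for each site, in-window in-interval neighbours and
# their interaction weights (unit prior coupling where no weight is known).
build_neighbors <- function(m, window, interval_index, weights = NULL) {
  wmap <- if (!is.null(weights) && nrow(weights)) {
    keys <- c(paste(weights$s1, weights$s2), paste(weights$s2, weights$s1))
    setNames(c(weights$omega, weights$omega), keys)
  } else character(0)
  purrr::map(seq_len(m), function(s) {
    idx <- setdiff(max(1L, s - window):min(m, s + window), s)
    idx <- idx[interval_index[idx] == interval_index[s]]
    if (!length(idx)) return(list(idx = integer(0), w = numeric(0)))
    w <- rep(1, length(idx))
    if (length(wmap)) {
      key <- paste(s, idx)
      hit <- key %in% names(wmap)
      w[hit] <- unname(wmap[key[hit]])
    }
    list(idx = idx, w = w)
  })
}

#' One ICM sweep over the causal-status vector
#'
#' Site-wise conditional maximisation of the pseudo-likelihood: site `s`
#' becomes causal when
#' \eqn{\lambda + \max(m_s, \text{floor}) + \tau B(P^e_s, P^b_s) + \nu J
#' \sum_{s'} \omega_{s,s'} (2 r_{s'} - 1) > 0}, holding the neighbour field
#' fixed. Non-candidate (common) sites never flip to causal.
#'
#' @param X Current causal-status vector (0/1).
#' @param m Solo evidence log-likelihood ratios.
#' @param p_e Per-site elevated probabilities.
#' @param r Region elevated posteriors (the neighbour field).
#' @param neighbors Neighbour structure from the fit (list of `idx`, `w`).
#' @param lambda Prior log-odds of causal status.
#' @param cand Candidate mask (rare sites).
#' @param config An [hmrf_config()].
#' @return List with updated `X` and the per-site `score`.
#' @export
icm_update_X <- function(X, m, p_e, r, neighbors, lambda, cand,
                         config = hmrf_config()) {
  m_len <- length(m)
  b_val <- if (config$b_form == "logodds") log(p_e / (1 - p_e)) else
    p_e - (1 - p_e)
  nbr <- vapply(seq_len(m_len), function(s) {
    nb <- neighbors[[s]]
    if (!length(nb$idx)) return(0)
    sum(nb$w * (2 * r[nb$idx] - 1))
  }, numeric(1))
  score <- lambda + pmax(m, config$m_floor) + config$tau * b_val +
    config$nu * config$coupling * nbr
  list(X = as.integer(score > 0 & cand), score = score)
}

#' Fit the hidden Markov random field selection model
#'
#' Alternates the E-step (scaled forward-backward over the region chain
#' within each four-gamete-compatible interval, pairwise posteriors), the
#' M-step (component carrier rates, case-share, mutation rate via
#' [em_update_mu()], persistence via [em_update_theta()], per-site elevated
#' probabilities) and ICM updates of the causal-status vector X, until the
#' parameter change drops below `tol`. A model-selection gate compares the
#' fitted two-component chain against a single-component null fit; when the
#' gate fails, no site is selected (this keeps the dataset-level false-report
#' rate of the downstream burden test near zero on null data).
#'
#' @param ds A `rare_dataset`.
#' @param weights Optional interaction-weight tibble from
#'   [interaction_weights()].
#' @param intervals Optional interval tibble from
#'   [find_compatible_intervals()]; computed from the data when `NULL`.
#' @param config An [hmrf_config()].
#' @return An object of class `hmrf_fit`; see [tidy.hmrf_fit()] and
#'   [glance.hmrf_fit()].
#' @examples
#' ds <- generate_dataset(sim_config(n_cases = 200, n_controls = 200,
#'                                   n_sites = 30, n_causal = 10,
#'                                   group_par = 0.05), seed = 3)
#' fit <- fit_hmrf(ds)
#' glance(fit)
#' @export
fit_hmrf <- function(ds, weights = NULL, intervals = NULL,
                     config = hmrf_config()) {
  stopifnot(inherits(ds, "rare_dataset"))
  carriers <- carrier_matrix(ds)
  case <- ds$labels == "case"
  a <- colSums(carriers[case, , drop = FALSE])
  b <- colSums(carriers[!case, , drop = FALSE])
  k <- a + b
  m <- length(k)
  n <- nrow(carriers)
  w0 <- sum(case) / n
  intervals <- intervals %||% find_compatible_intervals(ds)
  iv_index <- site_interval_index(intervals, m)
  segments <- split(seq_len(m), iv_index)
  neighbors <- build_neighbors(m, config$window, iv_index, weights)

  cand <- k / n <= config$rare_max
  # bounded per-site influence in the rate estimators: a single moderately
  # common site must not be able to drag the elevated component onto itself
  carrier_k <- k[cand & k > 0]
  winsor <- max(5, if (length(carrier_k))
    ceiling(stats::quantile(carrier_k, 0.9, names = FALSE)) else 0)
  kcap <- pmin(k, winsor)
  r <- ifelse(cand & k > 0 & a > b, 0.9, 0.1)
  p_e <- rep(config$pe0, m)
  theta <- config$theta0
  mu <- config$mu0
  loglik_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  rate_bg <- rate_e <- w1 <- NA_real_
  lme <- lmb <- numeric(m)

  for (it in seq_len(config$max_iter)) {
    iterations <- it
    old <- c(theta, mean(r))
    rc <- r * cand
    bc <- (1 - r) * cand
    rate_bg <- (sum(kcap * bc) + 0.25) / (n * sum(bc) + 1)
    rate_e <- max((sum(kcap * rc) + 0.25) / (n * sum(rc) + 1),
                  rate_bg * (1 + 1e-6))
    w1 <- min(max((sum(a * rc) + 2) / (sum(k * rc) + 4), w0), 0.999)
    ev <- site_evidence(a, k, n, w0, rate_bg, rate_e, w1, cand)
    lme <- ev$lme; lmb <- ev$lmb
    trans <- region_transition(theta, 1, 2)
    ll <- 0
    xis <- vector("list", length(segments))
    # the chain sees the same truncated solo potential as the ICM update:
    # bounded negative evidence keeps isolated zero-carrier sites rescuable
    lme_fb <- pmax(lme, lmb + config$m_floor)
    for (gi in seq_along(segments)) {
      seg <- segments[[gi]]
      mx <- pmax(lmb[seg], lme_fb[seg])
      emis <- cbind(exp(lmb[seg] - mx), exp(lme_fb[seg] - mx))
      prior_e <- min(max(mean(r), 0.02), 0.9)
      tab <- forward_backward_R(emis, trans, p_e = NULL,
                                prior = c(1 - prior_e, prior_e))
      r[seg] <- tab$posterior[, 2]
      xis[[gi]] <- xi_pairwise(tab)
      ll <- ll + tab$loglik + sum(mx)
    }
    loglik_trace <- c(loglik_trace, ll)
    theta <- em_update_theta(xis, distances = 1,
                             bounds = config$theta_bounds)
    p_e <- pmin(pmax(r, config$pe_eps), 1 - config$pe_eps)
    if (max(abs(c(theta, mean(r)) - old)) < config$tol && it > 1) {
      converged <- TRUE
      break
    }
  }

  lambda <- qlogis(min(max(mean(r), 0.02), 0.9))
  m_score <- lme - lmb
  X <- as.integer(r > 0.5 & cand)
  for (sw in seq_len(config$max_sweeps)) {
    upd <- icm_update_X(X, m_score, p_e, r, neighbors, lambda, cand, config)
    if (all(upd$X == X)) { X <- upd$X; break }
    X <- upd$X
  }
  score <- upd$score

  # mutation rate: posterior-weighted disagreement between the hidden
  # consensus (observed at causal sites, reference elsewhere) and G
  h_hat <- carriers
  h_hat[, X == 0L] <- 0L
  mu <- if (sum(k) > 0)
    em_update_mu(h_hat, carriers, posteriors = ifelse(X == 1L, r, 1 - r))
  else config$mu0

  # model-selection gate against the single-component null fit
  rate0 <- (sum(kcap[cand]) + 0.25) / (n * sum(cand) + 1)
  ll0 <- sum(dpois(k[cand], n * rate0, log = TRUE) +
               dbinom(a[cand], k[cand], w0, log = TRUE))
  ll_mix <- tail(loglik_trace, 1) - sum(lmb[!cand])
  gate <- 2 * (ll_mix - ll0)
  gate_pass <- gate > config$gate_mult * log(m)
  if (!gate_pass) X <- rep(0L, m)

  structure(list(
    X = X, selected_sites = which(X == 1L), r = r, m = m_score,
    p_e = p_e, score = score,
    params = list(mu = mu, theta = theta, rate_bg = rate_bg,
                  rate_e = rate_e, w1 = w1, pi = mean(r)),
    gate = gate, gate_pass = gate_pass, converged = converged,
    iterations = iterations, loglik_trace = loglik_trace,
    intervals = intervals, neighbors = neighbors, config = config,
    carriers = list(a = a, b = b, k = k, cand = cand),
    n_case = sum(case), n_control = sum(!case),
    site_ids = colnames(carriers) %||% sprintf("site%03d", seq_len(m))),
    class = "hmrf_fit")
}

#' @export
print.hmrf_fit <- function(x, ...) {
  cat("<hmrf_fit> ", length(x$X), " sites, ", length(x$selected_sites),
      " selected; gate ", round(x$gate, 1),
      if (x$gate_pass) " (passed)" else " (failed: no selection)",
      "; theta ", signif(x$params$theta, 3),
      "; converged ", x$converged, " in ", x$iterations, " iterations\n",
      sep = "")
  invisible(x)
}

#' Simulate a dataset from the region-chain generative model
#'
#' Draws a region chain with persistence `theta_region`, then per-site
#' carrier counts at the background or elevated rate with the elevated
#' case-share `w1`, and scatters the carriers over case/control samples.
#' Used for parameter-recovery checks and illustrations.
#'
#' @param m Number of sites.
#' @param n_samples Cohort size (half cases).
#' @param theta_region True persistence parameter.
#' @param rate_bg,rate_e Background and elevated per-sample carrier rates.
#' @param w1 Case share of carriers at elevated sites.
#' @param seed Optional integer seed.
#' @return A `rare_dataset` with the true region flags in
#'   `attr(, "region_truth")`.
#' @export
simulate_region_chain <- function(m = 100, n_samples = 2000,
                                  theta_region = 0.5, rate_bg = 2e-4,
                                  rate_e = 1e-3, w1 = 0.9, seed = NULL) {
  with_seed(seed, {
    trans <- region_transition(theta_region, 1, 2)
    rflag <- integer(m)
    rflag[1] <- rbinom(1, 1, 0.5)
    if (m > 1) for (s in 2:m)
      rflag[s] <- rbinom(1, 1, trans[rflag[s - 1] + 1L, 2])
    n_case <- n_samples %/% 2
    n_ctrl <- n_samples - n_case
    geno <- matrix(0L, n_samples, m)
    for (s in seq_len(m)) {
      rate <- if (rflag[s] == 1L) rate_e else rate_bg
      kk <- rbinom(1, n_samples, rate)
      if (kk == 0) next
      aa <- rbinom(1, kk, if (rflag[s] == 1L) w1 else n_case / n_samples)
      aa <- min(aa, n_case); bb <- min(kk - aa, n_ctrl)
      if (aa > 0) geno[sample.int(n_case, aa), s] <- 1L
      if (bb > 0) geno[n_case + sample.int(n_ctrl, bb), s] <- 1L
    }
    rownames(geno) <- sprintf("S%04d", seq_len(n_samples))
    colnames(geno) <- sprintf("site%03d", seq_len(m))
    ds <- new_rare_dataset(geno, rep(c("case", "control"), c(n_case, n_ctrl)),
                           integer(m), rep(rate_bg, m), rep(rate_e, m),
                           coding = "carrier")
    attr(ds, "region_truth") <- rflag
    ds
  })
}
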