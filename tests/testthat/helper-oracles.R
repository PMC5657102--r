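# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct quadrature and
# hand arithmetic only.

# Numeric CDF of the Wright density via log-substitution quadrature,
# independent of the package's tabulated inverse-CDF sampler.
oracle_wright_cdf <- function(sigma, beta_site, beta_repair) {
  # density of l = log(rho): exp(b_i * l) (1-e^l)^(b_L - 1) e^(-sigma e^l)
  dl <- function(l) exp(beta_site * l + (beta_repair - 1) * log1p(-exp(l)) -
                          sigma * exp(l))
  lo <- -750
  knots <- c(seq(lo, -14, length.out = 3000),
             seq(-14, log(1 - 1e-9), length.out = 60000)[-1])
  vals <- dl(knots)
  cells <- diff(knots) * (head(vals, -1) + tail(vals, -1)) / 2
  # analytic masses of the tails: below the grid floor the integrand is
  # exp(beta_i l) exactly, above 1 - 1e-9 it is the (1 - rho) power spike
  low <- exp(beta_site * lo) / beta_site
  top <- exp(-sigma) * (1e-9)^beta_repair / beta_repair
  total <- low + sum(cells) + top
  cum <- low + c(0, cumsum(cells))
  function(q) {
    vapply(q, function(x) {
      if (x <= 0) return(0)
      if (x >= 1) return(1)
      l <- log(x)
      if (l <= lo) return((exp(beta_site * l) / beta_site) / total)
      i <- findInterval(l, knots)
      frac <- if (i >= length(knots)) 1 else
        (l - knots[i]) / (knots[i + 1] - knots[i])
      extra <- if (i >= length(knots)) 0 else cells[i] * frac
      min((cum[i] + extra) / total, 1)
    }, numeric(1))
  }
}

# Brute-force path-sum posterior for a short chain: enumerate every state
# sequence, accumulate joint probabilities prior * prod(trans) * prod(emis).
oracle_chain_posterior <- function(emissions, transition, prior) {
  m <- nrow(emissions); j <- ncol(emissions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(j)), m)))
  probs <- apply(paths, 1, function(path) {
    p <- prior[path[1]] * emissions[1, path[1]]
    if (m > 1) for (s in 2:m)
      p <- p * transition[path[s - 1], path[s]] * emissions[s, path[s]]
    p
  })
  total <- sum(probs)
  post <- matrix(0, m, j)
  for (s in seq_len(m)) for (st in seq_len(j))
    post[s, st] <- sum(probs[paths[, s] == st]) / total
  pair <- if (m > 1) {
    arr <- array(0, dim = c(m - 1, j, j))
    for (s in seq_len(m - 1)) for (i in seq_len(j)) for (jj in seq_len(j))
      arr[s, i, jj] <- sum(probs[paths[, s] == i & paths[, s + 1] == jj]) / total
    arr
  }
  list(posterior = post, pairwise = pair, loglik = log(total))
}

# Kolmogorov-Smirnov distance of samples against a target CDF, conditioned
# on the range above `floor_q`: the power-law spike at 0 pushes mass below
# what double precision can represent, so the comparison is made on the
# representable conditional distribution.
oracle_ks_conditional <- function(x, cdf, floor_q = 1e-250) {
  keep <- sort(x[x > floor_q])
  n <- length(keep)
  f0 <- cdf(floor_q)
  u <- (cdf(keep) - f0) / (1 - f0)
  list(d = max(pmax(abs(u - (seq_len(n) - 1) / n),
                    abs(seq_len(n) / n - u))),
       n = n)
}

# Brute-force four-gamete check: enumerate the joint configurations.
oracle_four_gamete <- function(a, b) {
  configs <- unique(paste(a >= 1, b >= 1))
  length(configs) < 4
}

# Textbook 2x2 chi-squared statistic: n (ad - bc)^2 / product of margins.
oracle_chisq_2x2 <- function(tab) {
  a <- as.numeric(tab[1, 1]); b <- as.numeric(tab[1, 2])
  c <- as.numeric(tab[2, 1]); d <- as.numeric(tab[2, 2])
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Monte-Carlo permutation p-value for a 2x2 carrier table.
oracle_permutation_p <- function(carrier, is_case, n_perm = 2000, seed = 1) {
  set.seed(seed)
  obs <- oracle_chisq_2x2(matrix(c(sum(carrier[is_case]), sum(carrier[!is_case]),
                                   sum(is_case) - sum(carrier[is_case]),
                                   sum(!is_case) - sum(carrier[!is_case])),
                                 2, 2, byrow = TRUE))
  perm <- replicate(n_perm, {
    lab <- sample(is_case)
    oracle_chisq_2x2(matrix(c(sum(carrier[lab]), sum(carrier[!lab]),
                              sum(lab) - sum(carrier[lab]),
                              sum(!lab) - sum(carrier[!lab])),
                            2, 2, byrow = TRUE))
  })
  mean(perm >= obs - 1e-12)
}
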