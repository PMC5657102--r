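test_that("f_func is the saturating relaxation", {
  expect_identical(f_func(0, 10), 0)
  expect_equal(f_func(1e6, 4), 0.25)
  expect_equal(f_func(1, 4), (1 - exp(-1)) / 4, tolerance = 1e-12)
  expect_true(all(diff(f_func(seq(-2, 2, 0.5), 3)) > 0))
})

test_that("trans_H saturates at mu = 1 and favours agreement", {
  # d = 0, agreement: exponent is n (mu + (1 - mu) f(1, n))
  n <- 6; mu <- 0.2
  expect_equal(trans_H(mu, 1.5, 0, TRUE, n),
               exp(n * (mu + (1 - mu) * (1 - exp(-1)) / n)),
               tolerance = 1e-12)
  for (th in c(0.1, 1, 5)) for (d in c(0.5, 2))
    expect_equal(trans_H(1, th, d, TRUE, 4), trans_H(1, 7, 9, FALSE, 4))
  grid <- expand.grid(mu = c(0, 0.3, 0.9), th = c(0.2, 1, 4),
                      d = c(0.1, 1, 10))
  agree <- mapply(trans_H, grid$mu, grid$th, grid$d, TRUE, 8)
  disagree <- mapply(trans_H, grid$mu, grid$th, grid$d, FALSE, 8)
  expect_true(all(agree >= disagree))
})

test_that("trans_J channels behave at their limits", {
  expect_identical(trans_J(1.3, 0, 10),
                   c(duplicate = 1, permute = 0))
  # large N: the duplicate channel is dominated by exp(-theta d)
  tj <- trans_J(2, 3, 1e9)
  expect_equal(unname(tj["duplicate"]), exp(-6), tolerance = 1e-3)
  expect_identical(unname(tj["permute"]), 0)  # clipped non-positive channel
  # the permutation channel spreads f(-theta d) over N - 1 targets
  expect_equal((50 - 1) * f_func(-0.4, 50) / (50 - 1), f_func(-0.4, 50))
  expect_true(all(trans_J(5, 10, 4) >= 0 & trans_J(5, 10, 4) <= 1))
})

test_that("region_potential composes solo and interaction terms", {
  expect_identical(region_potential(log(0.5 / 0.5)), 1)
  expect_equal(region_potential(log(0.7 / 0.3), tau = 1, nu = 0),
               exp(log(0.7 / 0.3)), tolerance = 1e-12)
  expect_equal(region_potential(log(0.6 / 0.4), neighbor_r = 1, omega = 1),
               exp(0.5 * log(1.5) + 0.5), tolerance = 1e-10)
  expect_error(region_potential(0, tau = 0.7, nu = 0.7), "tau")
})

test_that("forward-backward matches brute-force path enumeration", {
  # M = 3, hand-chosen 2-state chain
  em <- rbind(c(0.9, 0.1), c(0.4, 0.6), c(0.2, 0.8))
  tr <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  prior <- c(0.5, 0.5)
  fb <- forward_backward_R(em, tr, prior = prior)
  oracle <- oracle_chain_posterior(em, tr, prior)
  expect_equal(fb$posterior, oracle$posterior, tolerance = 1e-12)
  expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-12)

  # random chains up to M = 8, 2 states
  for (seed in 1:6) {
    set.seed(seed)
    m <- sample(2:8, 1)
    em <- matrix(runif(m * 2, 0.05, 1), m, 2)
    a <- runif(1, 0.55, 0.95)
    tr <- matrix(c(a, 1 - a, 1 - a, a), 2, 2)
    fb <- forward_backward_R(em, tr)
    oracle <- oracle_chain_posterior(em, tr, c(0.5, 0.5))
    expect_equal(fb$posterior, oracle$posterior, tolerance = 1e-10)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
  }
})

test_that("trellis scaling keeps alpha.beta constant and normalised", {
  set.seed(4)
  em <- matrix(runif(60, 1e-4, 1), 30, 2)
  fb <- forward_backward_R(em, region_transition(0.8))
  expect_equal(rowSums(fb$alpha * fb$beta), rep(1, 30), tolerance = 1e-9)
  expect_equal(rowSums(fb$posterior), rep(1, 30), tolerance = 1e-9)
  # single site: posterior is the normalised prior-weighted emission
  one <- forward_backward_R(matrix(c(0.2, 0.6), 1), region_transition(1),
                            prior = c(0.25, 0.75))
  expect_equal(one$posterior[1, ],
               c(0.2 * 0.25, 0.6 * 0.75) / (0.2 * 0.25 + 0.6 * 0.75),
               tolerance = 1e-12)
  # uniform emissions + symmetric transitions: uniform posteriors
  unif <- forward_backward_R(matrix(1, 10, 2), region_transition(0.5))
  expect_equal(unif$posterior, matrix(0.5, 10, 2), tolerance = 1e-12)
})

test_that("the parity rule folds P^b / P^e into the emissions", {
  em <- rbind(c(0.5, 0.5), c(0.3, 0.7))
  pe <- c(0.9, 0.2)
  tr <- region_transition(1)
  fb <- forward_backward_R(em, tr, p_e = pe)
  manual <- forward_backward_R(em * cbind(1 - pe, pe), tr)
  expect_equal(fb$posterior, manual$posterior, tolerance = 1e-12)
})

test_that("pairwise posteriors are consistent joints", {
  em <- rbind(c(0.9, 0.1), c(0.4, 0.6), c(0.2, 0.8), c(0.5, 0.5))
  tr <- matrix(c(0.8, 0.2, 0.25, 0.75), 2, 2, byrow = TRUE)
  fb <- forward_backward_R(em, tr, prior = c(0.5, 0.5))
  xi <- xi_pairwise(fb)
  oracle <- oracle_chain_posterior(em, tr, c(0.5, 0.5))
  expect_equal(xi, oracle$pairwise, tolerance = 1e-10)
  # each slice is a normalised joint; marginalising recovers the posterior
  expect_equal(apply(xi, 1, sum), rep(1, 3), tolerance = 1e-9)
  for (s in 1:3)
    expect_equal(rowSums(xi[s, , ]), fb$posterior[s, ], tolerance = 1e-9)
  # a deterministic chain concentrates xi on a point mass
  em_det <- rbind(c(1, 1e-12), c(1, 1e-12))
  xi_det <- xi_pairwise(forward_backward_R(em_det, tr))
  expect_gt(xi_det[1, 1, 1], 1 - 1e-8)
})

test_that("the mutation-rate update is the weighted disagreement ratio", {
  g <- rbind(c(1L, 0L), c(1L, 1L))
  h_same <- g
  expect_identical(em_update_mu(h_same, g, c(1, 1)), 0)
  # hand toy: H = 0 at site 1 (both carriers disagree), H = G at site 2
  h <- g; h[, 1] <- 0L
  w <- c(0.5, 2)
  # num = 2 * 0.5 ; den = 2 * 0.5 + 1 * 2 (site 2 has a single carrier)
  expect_equal(em_update_mu(h, g, w), 1 / 3, tolerance = 1e-12)
  expect_equal(em_update_mu(h, g, w * 2), 1 / 3, tolerance = 1e-12)
  expect_error(em_update_mu(matrix(0L, 2, 2), matrix(0L, 2, 2), c(1, 1)),
               "All-reference")
})

test_that("the persistence update maximises the expected transition loglik", {
  set.seed(12)
  # build xi tables from a chain with known persistence
  em <- matrix(runif(40, 0.2, 1), 20, 2)
  theta_star <- 0.6
  fb <- forward_backward_R(em, region_transition(theta_star))
  xi <- xi_pairwise(fb)
  th <- em_update_theta(xi, bounds = c(0.05, 5))
  # grid oracle on the same objective
  flag <- c(0L, 1L)
  q_same <- apply(xi, 1, function(sl) sl[1, 1] + sl[2, 2])
  obj <- function(t) {
    stay <- exp(-t) + (1 - exp(-t)) / 2
    sum(q_same * log(stay) + (1 - q_same) * log(1 - stay))
  }
  grid <- seq(0.05, 5, length.out = 2000)
  expect_equal(th, grid[which.max(vapply(grid, obj, numeric(1)))],
               tolerance = 0.01)
  expect_warning(
    expect_identical(em_update_theta(array(0, c(0, 2, 2))), 0.05),
    "Degenerate")
})

test_that("the background-probability update follows the xi ratio", {
  xi <- array(0, c(2, 2, 2))
  xi[1, , ] <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  xi[2, , ] <- matrix(c(0, 0.2, 0.3, 0.5), 2, 2)
  up <- em_update_pb(xi, theta_region = 1, distances = 0, n = 5)
  # d = 0 makes the denominator exactly 1
  expect_equal(up$p_b[1], 0.4, tolerance = 1e-12)
  expect_equal(up$p_b[2], 1e-3, tolerance = 1e-12)  # clipped at eps
  expect_equal(up$p_b + up$p_e, rep(1, 3), tolerance = 1e-12)
})

test_that("fit recovers generative-chain parameters within MC tolerance", {
  reps <- 6
  theta_star <- 0.5; rate_bg <- 2e-4; rate_e <- 1.2e-3; w1 <- 0.9
  est <- purrr::map_dfr(seq_len(reps), function(i) {
    ds <- simulate_region_chain(m = 100, n_samples = 2000,
                                theta_region = theta_star,
                                rate_bg = rate_bg, rate_e = rate_e, w1 = w1,
                                seed = 400 + i)
    fit <- fit_hmrf(ds)
    truth <- attr(ds, "region_truth")
    k <- fit$carriers$k
    mu_truth <- sum(k[truth == 0]) / max(sum(k), 1)
    tibble::tibble(theta = fit$params$theta, rate_e = fit$params$rate_e,
                   w1 = fit$params$w1, mu = fit$params$mu,
                   mu_truth = mu_truth)
  })
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(est$theta) - theta_star), 3 * se(est$theta) + 0.1)
  expect_lt(abs(mean(est$rate_e) - rate_e), 3 * se(est$rate_e) + 2e-4)
  expect_lt(abs(mean(est$w1) - w1), 3 * se(est$w1) + 0.05)
  # the fitted mu agrees with the truth-based noise share of carrier mass
  expect_lt(abs(mean(est$mu) - mean(est$mu_truth)),
            3 * se(est$mu - est$mu_truth) + 0.05)
})

test_that("ICM selects separable causal sites and stays quiet at PAR zero", {
  # strongly separable: case-only carriers at high contrast
  set.seed(5)
  geno <- matrix(0L, 2000, 12)
  causal <- c(3, 4, 8)
  for (s in causal) geno[sample.int(1000, 10), s] <- 1L
  for (s in setdiff(1:12, causal)) geno[sample.int(2000, 1), s] <- 1L
  ds <- rareburden:::new_rare_dataset(
    geno, rep(c("case", "control"), each = 1000), integer(12),
    rep(1e-4, 12), rep(1e-3, 12), coding = "carrier")
  rownames(ds$genotypes) <- sprintf("S%04d", 1:2000)
  colnames(ds$genotypes) <- sprintf("site%03d", 1:12)
  fit <- fit_hmrf(ds)
  expect_true(all(causal %in% fit$selected_sites))

  # PAR = 0: no signal, selection stays (near) empty
  ds0 <- generate_dataset(sim_config(group_par = 0), seed = 71)
  fit0 <- fit_hmrf(ds0)
  expect_lt(length(fit0$selected_sites), 3)
})

test_that("single-site problems follow the marginal score", {
  geno <- matrix(0L, 200, 1)
  geno[1:8, 1] <- 1L   # all carriers are cases
  ds <- rareburden:::new_rare_dataset(
    geno, rep(c("case", "control"), each = 100), 0L, 1e-4, 1e-3,
    coding = "carrier")
  rownames(ds$genotypes) <- sprintf("S%03d", 1:200)
  colnames(ds$genotypes) <- "site001"
  fit <- suppressWarnings(fit_hmrf(ds))  # single-site theta is degenerate
  expect_identical(fit$X, as.integer(fit$score > 0 & fit$carriers$cand))
})

test_that("refitting from the fitted parameters is a fixed point", {
  ds <- generate_dataset(sim_config(group_par = 0.05), seed = 55)
  f1 <- fit_hmrf(ds)
  cfg2 <- hmrf_config(theta0 = f1$params$theta)
  f2 <- fit_hmrf(ds, intervals = f1$intervals, config = cfg2)
  expect_true(f1$converged)
  expect_lt(abs(f2$params$theta - f1$params$theta), 0.02)
  expect_identical(f2$X, f1$X)
})

test_that("selection is stable under site permutation on separable data", {
  cfg <- sim_config(n_cases = 500, n_controls = 500, n_sites = 30,
                    n_causal = 8, group_par = 0.4, maf_upper = 0.005)
  ds <- generate_dataset(cfg, seed = 17)
  fit <- fit_hmrf(ds)
  perm <- sample(30)
  ds_p <- ds
  ds_p$genotypes <- ds$genotypes[, perm]
  colnames(ds_p$genotypes) <- sprintf("site%03d", 1:30)
  ds_p$causal_truth <- ds$causal_truth[perm]
  fit_p <- fit_hmrf(ds_p)
  sel_back <- sort(perm[fit_p$selected_sites])
  expect_identical(sel_back, fit$selected_sites)
})

test_that("the pseudo-likelihood trace stabilises at convergence", {
  # the robustified M-steps trade strict EM monotonicity for stability, so
  # the check is stabilisation, not monotone ascent
  ds <- generate_dataset(sim_config(group_par = 0.03), seed = 88)
  fit <- fit_hmrf(ds)
  trace <- fit$loglik_trace
  expect_true(fit$converged)
  expect_lt(abs(diff(tail(trace, 2))), 0.5)
  expect_true(all(is.finite(trace)))
})
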