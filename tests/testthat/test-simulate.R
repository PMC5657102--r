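test_that("relative risk follows the marginal-PAR formula", {
  expect_identical(relative_risk(0, 0.01), 1)
  expect_equal(relative_risk(0.001, 0.01), 1 + 0.001 / (0.999 * 0.01),
               tolerance = 1e-12)
  # group PAR 0.02 split over 50 causal variants
  expect_equal(relative_risk(0.02 / 50, 0.005),
               1 + 0.0004 / (0.9996 * 0.005), tolerance = 1e-12)
  rhos <- c(0.001, 0.01, 0.1, 0.4)
  expect_true(all(diff(relative_risk(0.01, rhos)) < 0))
  expect_error(relative_risk(0.01, 0), "rho")
  expect_error(relative_risk(1, 0.01), "delta")
})

test_that("case MAF mapping is the RR lift and stays in (0, 1)", {
  expect_identical(case_maf(1, 0.01), 0.01)
  expect_equal(case_maf(2, 0.01), 0.02 / 1.01, tolerance = 1e-12)
  expect_true(all(case_maf(c(1, 10, 1e3, 1e9), 0.01) < 1))
  expect_true(all(diff(case_maf(c(1, 2, 5, 50), 0.01)) > 0))
  expect_error(case_maf(0.5, 0.01), "rr")
})

test_that("case MAF composed with RR reduces to delta + rho (1 - delta)", {
  grid <- expand.grid(delta = c(0, 1e-4, 4e-4, 0.01),
                      rho = c(1e-6, 1e-3, 0.05, 0.3))
  got <- case_maf(relative_risk(grid$delta, grid$rho), grid$rho)
  expect_equal(got, grid$delta + grid$rho * (1 - grid$delta),
               tolerance = 1e-10)
})

test_that("generate_dataset honours the fixed-number design", {
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_sites = 100,
                    n_causal = 50, group_par = 0.02)
  ds <- generate_dataset(cfg, seed = 21)
  expect_s3_class(ds, "rare_dataset")
  expect_identical(dim(ds$genotypes), c(2000L, 100L))
  expect_identical(sum(ds$causal_truth), 50L)
  expect_identical(ds$labels, rep(c("case", "control"), each = 1000))
  expect_true(all(ds$genotypes %in% 0:2))
  causal <- ds$causal_truth == 1
  expect_true(all(ds$case_mafs[causal] > ds$control_mafs[causal]))
  expect_true(all(ds$case_mafs[!causal] == ds$control_mafs[!causal]))
  expect_identical(generate_dataset(cfg, seed = 21)$genotypes, ds$genotypes)
})

test_that("a null PAR leaves case and control frequencies exchangeable", {
  cfg <- sim_config(n_cases = 2000, n_controls = 2000, n_sites = 200,
                    n_causal = 20, group_par = 0)
  ds <- generate_dataset(cfg, seed = 8)
  expect_true(all(ds$case_mafs == ds$control_mafs))
  carr <- carrier_matrix(ds)
  n_case <- sum(carr[ds$labels == "case", ])
  n_ctrl <- sum(carr[ds$labels == "control", ])
  # equal in expectation: binomial comparison of the two totals
  expect_gt(stats::binom.test(n_case, n_case + n_ctrl)$p.value, 1e-5)
})

test_that("the causal-site carrier frequency matches the two formulas", {
  cfg <- sim_config(n_cases = 20000, n_controls = 100, n_sites = 2,
                    n_causal = 1, group_par = 0.05)
  ds <- generate_dataset(cfg, seed = 31)
  s <- which(ds$causal_truth == 1)
  theta <- case_maf(relative_risk(0.05, ds$control_mafs[s]),
                    ds$control_mafs[s])
  expect_equal(theta, ds$case_mafs[s], tolerance = 1e-12)
  p_carrier <- 1 - (1 - theta)^2
  obs <- mean(carrier_matrix(ds)[ds$labels == "case", s])
  se <- sqrt(p_carrier * (1 - p_carrier) / 20000)
  expect_lt(abs(obs - p_carrier), 3 * se + 1e-9)
})

test_that("null datasets carry independent mutations and fair labels", {
  ds <- generate_null_dataset(1000, 100, 0.005, seed = 4)
  expect_identical(sum(ds$causal_truth), 0L)
  total <- sum(ds$genotypes)
  expect_lt(abs(total - 500), 5 * sqrt(500))
  expect_identical(generate_null_dataset(1000, 100, 0.005, seed = 4)$genotypes,
                   ds$genotypes)
  expect_true(all(generate_null_dataset(50, 10, 0, seed = 1)$genotypes == 0))
  labs <- unlist(lapply(1:20, function(i)
    generate_null_dataset(500, 2, 0.005, seed = i)$labels))
  frac <- mean(labs == "case")
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / length(labs)))
})

test_that("read-count overlay reflects carrier status and clone fractions", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, n_sites = 20,
                    n_causal = 10, group_par = 0.5, maf_upper = 0.2)
  ds <- generate_dataset(cfg, seed = 13)
  ov <- overlay_read_counts(ds, depth_mean = 100, error_rate = 0,
                            site_type = "germline", seed = 14)
  rc <- ov$read_counts
  expect_true(all(rc$tumor_support <= rc$tumor_depth))
  expect_true(all(rc$tumor_depth >= 1))
  carr <- carrier_matrix(ds) == 1
  expect_true(all(rc$tumor_support[!carr] == 0))  # error rate zero
  vaf <- rc$tumor_support[carr] / rc$tumor_depth[carr]
  expect_lt(abs(mean(vaf) - 0.5), 3 * sd(vaf) / sqrt(length(vaf)))

  # two sub-clones: per-site carrier VAF matches the assigned clone fraction
  ov2 <- overlay_read_counts(ds, depth_mean = 200, error_rate = 0,
                             site_type = "somatic", tumor_vaf = c(0.4, 0.1),
                             seed = 15)
  clone <- attr(ov2$read_counts, "clone_vaf")
  v <- vaf_estimates(ov2$read_counts)
  for (s in which(colSums(carr) >= 20)) {
    mv <- mean(v$tumor_vaf[carr[, s], s])
    expect_lt(abs(mv - clone[s]), 0.05)
  }
  expect_true(all(ov2$read_counts$normal_support == 0))
})
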