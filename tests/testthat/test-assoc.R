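toy_dataset <- function(geno, labels) {
  rownames(geno) <- sprintf("S%03d", seq_len(nrow(geno)))
  colnames(geno) <- sprintf("site%03d", seq_len(ncol(geno)))
  rareburden:::new_rare_dataset(geno, labels, integer(ncol(geno)),
                                rep(0.01, ncol(geno)), rep(0.01, ncol(geno)),
                                coding = "carrier")
}

test_that("collapsing matches a brute-force any() scan", {
  set.seed(3)
  geno <- matrix(rbinom(50 * 6, 1, 0.2), 50, 6)
  labels <- rep(c("case", "control"), length.out = 50)
  ds <- toy_dataset(geno, labels)
  sel <- c(2L, 5L)
  tab <- collapse_variants(ds, sel)
  carrier <- apply(geno[, sel], 1, function(row) any(row > 0))
  expect_identical(tab["carrier", "case"], sum(carrier[labels == "case"]))
  expect_identical(tab["carrier", "control"],
                   sum(carrier[labels == "control"]))
  expect_identical(colSums(tab), c(case = 25, control = 25))
  # a single site reproduces its own carrier table
  one <- collapse_variants(ds, 4L)
  expect_identical(unname(one["carrier", ]),
                   unname(c(sum(geno[labels == "case", 4]),
                            sum(geno[labels == "control", 4]))))
  # two sites with disjoint carrier sets add up
  g2 <- matrix(0L, 10, 2); g2[1:3, 1] <- 1L; g2[6:7, 2] <- 1L
  ds2 <- toy_dataset(g2, rep("case", 10))
  expect_equal(unname(collapse_variants(ds2, 1:2)["carrier", "case"]), 5)
  # empty selection: an all-zero carrier row
  expect_equal(unname(collapse_variants(ds, integer(0))["carrier", ]), c(0, 0))
})

test_that("the burden test follows the textbook chi-squared", {
  even <- matrix(c(50, 50, 950, 950), 2, 2, byrow = TRUE,
                 dimnames = list(c("carrier", "non_carrier"),
                                 c("case", "control")))
  bt <- burden_test(even)
  expect_identical(bt$statistic, 0)
  expect_identical(bt$p_value, 1)
  tab <- matrix(c(100, 50, 900, 950), 2, 2, byrow = TRUE)
  bt2 <- burden_test(tab)
  expect_equal(bt2$statistic, oracle_chisq_2x2(tab), tolerance = 1e-10)
  expect_equal(bt2$p_value, pchisq(oracle_chisq_2x2(tab), 1,
                                   lower.tail = FALSE), tolerance = 1e-10)
  expect_identical(bt2$method, "chisq")
  # small expected cells fall back to Fisher
  small <- matrix(c(4, 0, 96, 100), 2, 2, byrow = TRUE)
  expect_identical(burden_test(small)$method, "fisher")
  # degenerate margins
  none <- matrix(c(0, 0, 100, 100), 2, 2, byrow = TRUE)
  expect_identical(burden_test(none)$p_value, 1)
})

test_that("the chi-squared p agrees with a label-permutation oracle", {
  # 145 of 600 case carriers vs 120 of 600 control carriers: a mid-range p
  # where the chi-squared approximation should track the permutation law
  is_case <- rep(c(TRUE, FALSE), each = 600)
  carrier <- c(rep(c(TRUE, FALSE), c(145, 455)),
               rep(c(TRUE, FALSE), c(120, 480)))
  tab <- matrix(c(sum(carrier[is_case]), sum(carrier[!is_case]),
                  sum(is_case) - sum(carrier[is_case]),
                  sum(!is_case) - sum(carrier[!is_case])),
                2, 2, byrow = TRUE)
  p_chisq <- burden_test(tab)$p_value
  p_perm <- oracle_permutation_p(carrier, is_case, n_perm = 4000)
  expect_lt(abs(p_chisq - p_perm),
            3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.02)
})

test_that("significance thresholds are strict and mode-dependent", {
  expect_true(declare_significance(0.04, "simulation"))
  expect_false(declare_significance(0.05, "simulation"))
  expect_false(declare_significance(1e-5, "exome"))
  expect_true(declare_significance(1e-7, "exome"))
  expect_false(declare_significance(2.5e-6, "exome"))
})

test_that("assoc_test wires selection into the table", {
  geno <- matrix(0L, 200, 4)
  geno[1:20, 2] <- 1L  # cases only
  ds <- toy_dataset(geno, rep(c("case", "control"), each = 100))
  res <- assoc_test(ds, 2L)
  expect_equal(res$carriers_case, 20)
  expect_equal(res$carriers_control, 0)
  expect_true(res$significant)
  empty <- assoc_test(ds, integer(0))
  expect_identical(empty$p_value, 1)
  expect_false(empty$significant)
})

test_that("evaluate_replicates applies the selection-level definitions", {
  perfect <- tibble::tibble(
    significant = c(TRUE, TRUE),
    selected = list(c(1L, 2L), c(3L)),
    truth = list(c(1, 1, 0, 0), c(0, 0, 1, 0)))
  ev <- evaluate_replicates(perfect)
  expect_identical(ev$power, 1)
  expect_identical(ev$type_i, 0)
  expect_identical(ev$type_ii, 0)
  inverted <- tibble::tibble(
    significant = FALSE,
    selected = list(c(3L, 4L)),
    truth = list(c(1, 1, 0, 0)))
  ev2 <- evaluate_replicates(inverted)
  expect_identical(ev2$power, 0)
  expect_identical(ev2$type_i, 1)
  expect_identical(ev2$type_ii, 1)
  # hand-built 3-dataset fixture
  hand <- tibble::tibble(
    significant = c(TRUE, FALSE, TRUE),
    selected = list(c(1L, 3L), integer(0), c(2L, 4L)),
    truth = list(c(1, 1, 0, 0),        # 1 of 2 causal missed; 1 of 2 neutral
                 c(1, 0, 0, 0),        # the causal one missed
                 c(0, 1, 1, 0)))       # 1 of 2 causal missed; 1 of 2 neutral
  ev3 <- evaluate_replicates(hand)
  expect_identical(ev3$power, 2 / 3)
  expect_equal(ev3$type_i, mean(c(1 / 2, 1, 1 / 2)), tolerance = 1e-12)
  expect_equal(ev3$type_ii, mean(c(1 / 2, 0, 1 / 2)), tolerance = 1e-12)
})
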