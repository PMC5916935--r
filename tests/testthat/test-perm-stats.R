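test_that("Welch statistic matches its closed form and handles degeneracy", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(welch_t(c(1, 2, 3), c(4, 5, 6)), -3 / sqrt(2 / 3))
  # cross-check against the standard implementation on random data
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(8)
    expect_equal(welch_t(x, y), unname(t.test(x, y)$statistic),
                 tolerance = 1e-12)
  }
  # scale equivariance of |t|
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(abs(welch_t(3 * x, 3 * y)), abs(welch_t(x, y)),
               tolerance = 1e-12)
  # degenerate: zero variance both sides
  expect_equal(welch_t(c(2, 2), c(2, 2)), 0)
  expect_identical(welch_t(c(3, 3), c(1, 1)), Inf)
  expect_error(welch_t(1, c(1, 2)), class = "mlacdiff_stat_error")
})

test_that("exhaustive permutation p equals brute-force enumeration (n <= 12)", {
  # frozen worked example: clear separation, C(6,3) = 20 relabelings, the
  # observed split and its mirror are the only ones as extreme
  expect_equal(permutation_pvalue(c(1, 2, 3), c(10, 11, 12)), 2 / 20)

  set.seed(41)
  for (i in 1:12) {
    nx <- sample(3:6, 1)
    ny <- sample(3:6, 1)
    x <- rnorm(nx)
    y <- rnorm(ny, mean = sample(c(0, 1), 1))
    expect_identical(permutation_pvalue(x, y), brute_perm_p(x, y))
  }
  # with ties in the data
  x <- c(1, 1, 2, 2); y <- c(2, 2, 3)
  expect_identical(permutation_pvalue(x, y), brute_perm_p(x, y))
})

test_that("all-identical data give p = 1", {
  expect_equal(permutation_pvalue(rep(4, 3), rep(4, 3)), 1)
})

test_that("Monte Carlo estimate agrees with the exhaustive p", {
  x <- c(0.3, 1.2, -0.5, 0.8)
  y <- c(1.9, 2.4, 1.1, 3.0)
  p_ex <- permutation_pvalue(x, y)                      # C(8,4) = 70
  p_mc <- permutation_pvalue(x, y, cap = 1, n_perm = 10000, seed = 7)
  expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / 10000) + 2e-4)
})

test_that("permutation p is symmetric under group-label swap", {
  set.seed(13)
  x <- rnorm(5); y <- rnorm(7, 1)
  expect_identical(permutation_pvalue(x, y), permutation_pvalue(y, x))
  expect_equal(welch_t(x, y), -welch_t(y, x))
})

test_that("eligibility requires three quantified samples in both groups", {
  q <- dplyr::bind_rows(
    make_quant("G1", "UNB", bph = rnorm(3), pca = rnorm(3)),
    make_quant("G2", "UNB", bph = rnorm(2), pca = rnorm(10)),
    make_quant("G3", "PHA", pca = rnorm(5))
  )
  el <- eligibility_filter(q)
  expect_true(el$eligible[el$gene == "G1"])
  expect_false(el$eligible[el$gene == "G2"])   # n_bph = 2 < 3
  expect_false(el$eligible[el$gene == "G3"])   # never detected in BPH
  expect_equal(el$n_bph[el$gene == "G3"], 0)
})

test_that("permutation FDR has the defining boundary and monotonicity properties", {
  # single feature with p below every permuted p
  out <- permutation_fdr(0.001, matrix(runif(200, 0.01, 1), nrow = 1))
  expect_equal(out$fdr, 0)

  # monotone non-decreasing after sorting by p
  set.seed(5)
  obs <- runif(40)
  perm <- matrix(runif(40 * 30), nrow = 40)
  fd <- permutation_fdr(obs, perm)
  expect_true(all(diff(fd$fdr[order(fd$p)]) >= 0))
  expect_true(all(fd$fdr >= 0 & fd$fdr <= 1))
  expect_true(all(fd$fdr <= fd$fdr_raw + 1e-12))

  # pure null: almost nothing clears a 1% FDR bound
  set.seed(6)
  obs0 <- runif(200)
  perm0 <- matrix(runif(200 * 50), nrow = 200)
  fd0 <- permutation_fdr(obs0, perm0)
  expect_lte(mean(fd0$fdr <= 0.01), 0.02)

  expect_equal(nrow(permutation_fdr(numeric(0), matrix(0, 0, 5))), 0)
})

test_that("compare_groups reports delta as PCa minus BPH group means", {
  # group means fixed by construction: symmetric spread around the target
  q <- dplyr::bind_rows(
    make_quant("SPARC", "UNB", bph = 1.58 + c(-0.2, 0, 0.2),
               pca = 2.58 + c(-0.1, 0, 0.1)),
    make_quant("CD163", "PHA", bph = -0.610 + c(-0.3, 0, 0.3),
               pca = 0.373 + c(-0.2, 0, 0.2))
  )
  cmp <- tidy(compare_groups(q, seed = 1))
  expect_equal(cmp$delta[cmp$gene == "SPARC"], 1.00, tolerance = 1e-12)
  expect_equal(cmp$delta[cmp$gene == "CD163"], 0.983, tolerance = 1e-12)
})

test_that("identical group values give delta 0 and p = 1", {
  v <- c(0.1, 0.5, 0.9)
  q <- make_quant("G1", "UNB", bph = v, pca = v)
  cmp <- tidy(compare_groups(q, seed = 1))
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("swapping group labels negates delta and preserves p", {
  co <- generate_cohort(tiny_design())
  q <- quantify_evidence(co$evidence)
  fit1 <- tidy(compare_groups(q, seed = 3, fdr_perms = 0))
  q_swap <- q %>%
    dplyr::mutate(group = ifelse(group == "PCa", "BPH", "PCa"))
  fit2 <- tidy(compare_groups(q_swap, seed = 3, fdr_perms = 0))
  expect_equal(fit2$delta, -fit1$delta)
  expect_equal(fit2$p_value, fit1$p_value)
})

test_that("ineligible features keep means but no p-value or FDR", {
  q <- dplyr::bind_rows(
    make_quant("G1", "UNB", bph = rnorm(2), pca = rnorm(5)),
    make_quant("G2", "UNB", bph = rnorm(4), pca = rnorm(5))
  )
  cmp <- tidy(compare_groups(q, seed = 1))
  g1 <- cmp[cmp$gene == "G1", ]
  expect_false(g1$eligible)
  expect_false(is.na(g1$mean_bph))
  expect_true(is.na(g1$p_value) && is.na(g1$fdr))
  expect_false(is.na(cmp$p_value[cmp$gene == "G2"]))
})

test_that("compare_groups is deterministic for a given seed and ignores row order", {
  co <- generate_cohort(tiny_design())
  q <- quantify_evidence(co$evidence)
  f1 <- tidy(compare_groups(q, seed = 9))
  f2 <- tidy(compare_groups(q[withr::with_seed(2, sample(nrow(q))), ], seed = 9))
  expect_equal(f1, f2)
})

test_that("fold-change flag gates on the absolute PCa group mean", {
  q <- dplyr::bind_rows(
    make_quant("UP", "UNB", bph = c(0, 0, 0), pca = c(0.7, 0.8, 0.9)),
    make_quant("DOWN", "UNB", bph = c(0, 0, 0), pca = c(-0.7, -0.8, -0.9)),
    make_quant("FLAT", "UNB", bph = c(-0.6, 0, 0.6), pca = c(0.1, 0.2, 0.3))
  )
  cmp <- tidy(compare_groups(q, seed = 1))
  expect_true(cmp$fc_flag[cmp$gene == "UP"])
  expect_true(cmp$fc_flag[cmp$gene == "DOWN"])   # |mean| gate, sign-blind
  expect_false(cmp$fc_flag[cmp$gene == "FLAT"])  # 0.2 < 0.585
})

test_that("glance summarises the fit in one row", {
  co <- generate_cohort(tiny_design())
  fit <- compare_groups(quantify_evidence(co$evidence), seed = 1,
                        fdr_perms = 20)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_features, nrow(tidy(fit)))
  expect_lte(g$n_significant_global, g$n_significant)
})
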