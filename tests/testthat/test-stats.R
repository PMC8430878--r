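test_that("exact rank-sum p-values equal brute-force enumeration", {
  expect_equal(wilcoxon_compare(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  set.seed(42)
  for (n in 2:6) for (m in 2:6) {
    a <- stats::rnorm(n); b <- stats::rnorm(m, 0.5)
    got <- wilcoxon_compare(a, b)
    expect_true(got$exact)
    expect_equal(got$p_value, rank_sum_exact_p(a, b), tolerance = 1e-12,
                 label = sprintf("n=%d m=%d", n, m))
  }
})

test_that("identical groups give p = 1 and tiny groups are rejected", {
  expect_equal(wilcoxon_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(wilcoxon_compare(1, c(1, 2)), "at least 2")
})

test_that("Spearman correlation handles perfect and near-perfect ranks", {
  x <- 1:8
  expect_equal(spearman_corr(x, x)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  expect_equal(spearman_corr(x, -x)$category, "strong")
  # one adjacent swap: rho = 1 - 6*sum(d^2)/(n(n^2-1)) with d^2 = 2
  y <- c(1, 2, 3, 5, 4, 6, 7, 8)
  expect_equal(spearman_corr(x, y)$rho, 1 - 6 * 2 / (8 * 63),
               tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  base <- spearman_corr(x, y)$rho
  expect_equal(spearman_corr(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_corr(x, y^3)$rho, base, tolerance = 1e-12)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  # incomplete pairs are dropped
  xm <- c(x, NA); ym <- c(y, 1)
  expect_equal(spearman_corr(xm, ym)$n, 20)
})

test_that("correlation categories follow the |rho| bands", {
  expect_equal(spearman_corr(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))$category,
               "strong")   # rho = 0.952
  expect_equal(spearman_corr(1:6, c(2, 4, 1, 6, 3, 5))$category, "moderate")
  expect_equal(spearman_corr(1:5, c(3, 1, 5, 2, 4))$category, "weak")
})

test_that("percent change matches the published worked examples", {
  ref <- reference_cohort_summary()
  ifv <- ref$ifv_ms_mean
  expect_lt(abs(percent_change(ifv[1], ifv[2]) - 48), 1.5)
  expect_lt(abs(percent_change(ifv[1], ifv[3]) - 21), 1.5)
  expect_lt(abs(percent_change(ifv[2], ifv[3]) - (-18)), 1.5)
  ifp <- ref$ifp_kpa_mean
  expect_lt(abs(percent_change(ifp[1], ifp[2])), 3)
  expect_lt(abs(percent_change(ifp[1], ifp[3])), 3)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "zero")
})

test_that("percent change is antisymmetric about the reference", {
  a <- 2.63
  for (b in c(1.9, 2.5, 3.3)) {
    expect_equal(percent_change(a, b), -percent_change(a, 2 * a - b),
                 tolerance = 1e-12)
  }
})

test_that("cohort tables are permutation-invariant and complete", {
  set.seed(3)
  rows <- do.call(rbind, lapply(1:6, function(s) {
    tibble::tibble(subject = sprintf("s%02d", s),
                   timepoint = c("pre-TX", "D1-TX", "D2-TX"),
                   vt_cm3 = stats::runif(3, 2, 40),
                   ktrans_mean = c(0.14, 0.27, 0.19) + stats::rnorm(3, 0, 0.02),
                   ktrans_sd = 0.01,
                   ifp_kpa_mean = stats::rnorm(3, 2.6, 0.2), ifp_kpa_sd = 0.1,
                   ifv_ms_mean = stats::rnorm(3, 1.4e-7, 2e-8),
                   ifv_ms_sd = 1e-8)
  }))
  t1 <- cohort_table(rows)
  t2 <- cohort_table(rows[sample(nrow(rows)), ])
  expect_identical(t1$report, t2$report)
  expect_equal(t1$by_timepoint, t2$by_timepoint)
  expect_equal(t1$wilcoxon, t2$wilcoxon)
  expect_equal(nrow(t1$by_timepoint), 3)
  expect_setequal(unique(t1$wilcoxon$metric), c("ktrans", "ifp", "ifv"))
  expect_true(any(grepl("multiple-testing", t1$notes)))
})

test_that("a single-subject table reports zero SDs and skips tests", {
  row <- tibble::tibble(subject = "s01", timepoint = "pre-TX", vt_cm3 = 10,
                        ktrans_mean = 0.14, ktrans_sd = 0.01,
                        ifp_kpa_mean = 2.6, ifp_kpa_sd = 0.1,
                        ifv_ms_mean = 1.2e-7, ifv_ms_sd = 1e-8)
  out <- cohort_table(row)
  expect_equal(out$by_timepoint$ktrans_sd, 0)
  expect_null(out$wilcoxon)
  expect_true(any(grepl("skipped", out$notes)))
})
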