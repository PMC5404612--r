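test_that("delta_bp computes the signed percent reduction", {
  expect_equal(delta_bp(2.5, 2.0), 20.0)
  expect_equal(delta_bp(2.5, 2.5), 0.0)
  expect_equal(delta_bp(2.0, 2.1), -5.0)
  expect_equal(delta_bp(2.5, 2.0, fractional = TRUE), 0.2)
  expect_warning(out <- delta_bp(0, 1), "undefined")
  expect_true(is.na(out))
})

test_that("delta_bp round-trips the simulator's truth encoding and is scale-free", {
  for (d in c(-5, 0, 6.1, 17.1, 50)) {
    expect_equal(delta_bp(2.5, 2.5 * (1 - d / 100)), d, tolerance = 1e-12)
  }
  expect_equal(delta_bp(2.5, 2.0), delta_bp(7.5, 6.0))
})

test_that("test-retest variability is symmetric and matches hand arithmetic", {
  expect_equal(test_retest_variability(c(2, 3), c(2, 3)), 0)
  expect_equal(test_retest_variability(2.0, 2.2), 100 * 0.2 / 2.1)
  a <- c(2.1, 2.6, 3.0); b <- c(2.0, 2.9, 2.7)
  expect_equal(test_retest_variability(a, b), test_retest_variability(b, a))
  expect_error(test_retest_variability(1:3, 1:2), "mismatch")
  expect_error(test_retest_variability(c(2, -1), c(2, 1)), "positive")
})

test_that("test-retest variability grows with simulator noise", {
  trv_at <- function(ns, seed) {
    cfg <- fx_config(n_subjects = 4, seed = seed, noise_scale = ns)
    coh <- simulate_cohort(cfg)
    bp <- fit_cohort_bp(coh$scans, coh$tacs, refine = "interp")
    test_retest_report(bp)$mean_abs_percent_var
  }
  seeds <- 1:5
  v1 <- mean(vapply(seeds, function(s) trv_at(0.05, s), numeric(1)))
  v2 <- mean(vapply(seeds, function(s) trv_at(0.1, s), numeric(1)))
  v3 <- mean(vapply(seeds, function(s) trv_at(0.2, s), numeric(1)))
  expect_true(v1 < v2 && v2 < v3)
})

test_that("ICC(1,1) matches the one-way ANOVA decomposition", {
  set.seed(11)
  m <- matrix(rnorm(16, mean = rep(rnorm(8, 3, 0.5), 2), sd = 0.1), ncol = 2)
  # independent oracle: variance components via stats::aov
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(8), 2)))
  ms <- summary(stats::aov(y ~ subj, data = long))[[1]][["Mean Sq"]]
  icc_oracle <- (ms[1] - ms[2]) / (ms[1] + ms[2])
  expect_equal(icc_baseline(m), icc_oracle, tolerance = 1e-12)
})

test_that("ICC is 1 for duplicated columns and ~0 under the null", {
  x <- c(2.1, 2.8, 3.3, 1.9, 2.5)
  expect_equal(icc_baseline(cbind(x, x)), 1)
  set.seed(21)
  null_icc <- vapply(1:200, function(i) {
    icc_baseline(matrix(rnorm(16, mean = 3, sd = 0.2), ncol = 2))
  }, numeric(1))
  expect_lt(abs(mean(null_icc)), 0.15)
  expect_warning(icc_baseline(matrix(2, 4, 2)), "zero total variance")
  expect_error(icc_baseline(matrix(1:2, 1, 2)), ">= 2 subjects")
})

test_that("signed-rank p-values match the exact enumeration and wilcox.test", {
  # all-positive differences 1,2,3: one-sided tail 1/8, two-sided 1/4
  r <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$p, 0.25)
  expect_true(r$exact)
  # identical vectors: all differences zero
  r0 <- wilcoxon_signed_rank(c(1, 2), c(1, 2))
  expect_equal(r0$p, 1)
  expect_true(r0$all_zero)
  # negating differences leaves the two-sided p unchanged
  set.seed(5)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(a, b)$p, wilcoxon_signed_rank(b, a)$p)
  # independent oracle: stats::wilcox.test exact p on tie-free data
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(wilcoxon_signed_rank(x, y)$p,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("delta_bp_table pairs baselines with post scans within session", {
  bp <- data.frame(
    subject = rep("s1", 4), session = c(1, 1, 2, 2),
    scan_type = rep(c("baseline", "post"), 2),
    condition = rep(c("MP+LPS", "MP+PBO"), each = 2),
    region = "striatum", bp = c(2.5, 2.0, 2.4, 2.2))
  d <- delta_bp_table(bp)
  expect_equal(nrow(d), 2)
  expect_equal(d$delta_bp[d$condition == "MP+LPS"], 20)
  expect_equal(d$delta_bp[d$condition == "MP+PBO"], 100 * 0.2 / 2.4)
  expect_error(delta_bp_table(bp[-1, ]), "matching baseline")
})
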