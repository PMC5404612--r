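test_that("paired t matches the closed form and is antisymmetric", {
  a <- c(2, 3, 4); b <- c(1, 1, 1)   # differences 1, 2, 3
  r <- paired_ttest(a, b)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)  # 3.4641
  expect_equal(r$p, 2 * pt(-r$t, df = 2))
  expect_equal(round(r$p, 4), 0.0742)
  r2 <- paired_ttest(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  rz <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(rz$degenerate)
  expect_true(is.na(rz$p))
})

test_that("paired t holds its nominal type-I error at n=8", {
  set.seed(123)
  reps <- 2000
  rej <- vapply(seq_len(reps), function(i) {
    paired_ttest(rnorm(8), rnorm(8))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("bonferroni threshold is alpha/m and monotone", {
  expect_equal(bonferroni_threshold(0.05, 6), 0.05 / 6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  ms <- 1:10
  expect_true(all(diff(vapply(ms, function(m)
    bonferroni_threshold(0.05, m), numeric(1))) < 0))
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})

test_that("pearson screen is affine-invariant and flags degeneracy", {
  set.seed(7)
  x <- rnorm(10); y <- rnorm(10)
  r1 <- pearson_screen(x, y)
  r2 <- pearson_screen(2 * x + 5, 0.3 * y - 1)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(pearson_screen(x, x)$r, 1)
  expect_true(pearson_screen(rep(1, 5), rnorm(5))$degenerate)
})

test_that("voxelwise contrast flags direction and respects bounds", {
  dims <- c(4, 4, 2)
  set.seed(31)
  mk <- function(shift) {
    lapply(1:6, function(i) array(rnorm(prod(dims)) + shift, dims))
  }
  a <- mk(2); b <- mk(0)
  sig <- voxelwise_contrast(a, b)
  expect_true(all(sig$one_minus_p[sig$valid] >= 0 &
                  sig$one_minus_p[sig$valid] <= 1))
  expect_true(all(sig$direction[sig$displayed] == 1))
  # identical per-subject images: nothing displayed
  sig0 <- voxelwise_contrast(a, a)
  expect_equal(sum(sig0$displayed), 0)
  expect_error(voxelwise_contrast(a, b[1:3]), "mismatch")
})

test_that("percent significant voxels equals brute-force counting on a toy mask", {
  labels <- array(0L, c(3, 3, 3))
  labels[1:2, 1, 1] <- 3L   # putamen_l: 2 voxels
  labels[3, 1, 1] <- 4L     # putamen_r: 1 voxel
  toy_phantom <- structure(list(labels = labels,
                                label_map = phantom_labels()),
                           class = "label_phantom")
  displayed <- array(FALSE, c(3, 3, 3)); displayed[1, 1, 1] <- TRUE
  valid <- array(FALSE, c(3, 3, 3)); valid[1:3, 1, 1] <- TRUE
  sig <- structure(list(displayed = displayed, valid = valid),
                   class = "significance_map")
  expect_equal(percent_significant_voxels(sig, toy_phantom, "putamen_l"), 50)
  expect_equal(percent_significant_voxels(sig, toy_phantom, "putamen"),
               100 * 1 / 3)
  expect_equal(percent_significant_voxels(sig, toy_phantom, "putamen_r"), 0)
  expect_error(percent_significant_voxels(sig, toy_phantom, "cerebellum"),
               "empty region")
})

test_that("the region report table has the canonical 10-row layout", {
  set.seed(41)
  regions <- c("striatum", "putamen", "putamen_l", "putamen_r",
               "caudate", "caudate_l", "caudate_r",
               "ventral_striatum", "ventral_striatum_l", "ventral_striatum_r")
  dbp <- expand.grid(subject = sprintf("s%d", 1:8),
                     condition = c("MP+LPS", "MP+PBO"),
                     region = regions, stringsAsFactors = FALSE)
  dbp$delta_bp <- rnorm(nrow(dbp), 12, 4)
  tab <- build_table1(dbp)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$region, regions)
  expect_true(all(is.finite(tab$p_paired)))
  # order-stable under input shuffling
  tab2 <- build_table1(dbp[sample(nrow(dbp)), ])
  expect_equal(tab, tab2)
  # a condition without within-subject pairs stays descriptive
  lps <- data.frame(subject = c("s9", "s10"), condition = "LPS",
                    region = "striatum", delta_bp = c(5, 7.2))
  tab3 <- build_table1(rbind(dbp, lps))
  expect_equal(tab3$mean_lps[1], 6.1)
  expect_equal(tab3$n_lps[1], 2)
})

test_that("zero-SD noise-free cohorts report the configured truth with SD 0", {
  cfg <- fx_config(n_subjects = 2, seed = 13, noise_scale = 0,
                   conditions = list("MP+LPS" = list(mean = 15, sd = 0),
                                     "MP+PBO" = list(mean = 7, sd = 0)))
  coh <- simulate_cohort(cfg)
  bp <- fit_cohort_bp(coh$scans, coh$tacs)
  tab <- build_table1(delta_bp_table(bp))
  expect_equal(tab$mean_mp_lps, 15, tolerance = 0.01)
  expect_equal(tab$mean_mp_pbo, 7, tolerance = 0.01)
  expect_lt(tab$sd_mp_lps, 0.01)
})
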