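test_that("exponential convolution matches the analytic closed form", {
  sched <- fx_sched()
  a <- 0.1; k2a <- 0.25
  t <- seq(0, 120, by = 0.05)
  ref <- fine_tac(t, exp(-a * t))
  got <- exp_convolve(ref, k2a, sched)
  # conv = (e^{-at} - e^{-k2a t}) / (k2a - a); frame-average analytically
  anti <- function(tt) (-exp(-a * tt) / a + exp(-k2a * tt) / k2a) / (k2a - a)
  want <- (anti(sched$end) - anti(sched$start)) / sched$dur
  expect_lt(max(abs(got - want)), 1e-4)
})

test_that("convolution is linear and vanishes for a zero reference", {
  sched <- fx_sched()
  t <- seq(0, 120, by = 0.05)
  z <- exp_convolve(fine_tac(t, rep(0, length(t))), 0.1, sched)
  expect_true(all(z == 0))
  ref <- fx_ref()
  b1 <- exp_convolve(ref, 0.1, sched)
  ref2 <- fine_tac(ref$t, 2 * ref$y)
  expect_equal(exp_convolve(ref2, 0.1, sched), 2 * b1, tolerance = 1e-12)
})

test_that("large k2a makes the basis approach ref/k2a for slow references", {
  sched <- fx_sched()
  # dt must resolve 1/k2a for the quadrature to see the asymptote
  ref <- simulate_reference_tac(fine_dt = 0.005)
  b <- exp_convolve(ref, 10, sched)
  refF <- frame_average(ref, sched)
  late <- sched$mid > 30   # slowly varying tail
  expect_equal(b[late], refF[late] / 10, tolerance = 0.01)
})

test_that("convolution rejects bad inputs", {
  sched <- fx_sched()
  expect_error(exp_convolve(fx_ref(), -1, sched), "positive")
  coarse <- fine_tac(seq(0, 120, by = 1), rep(1, 121))
  expect_error(exp_convolve(coarse, 0.1, sched), "coarser")
})

test_that("weights are duration- and decay-scaled and normalised", {
  sched <- fx_sched()
  w <- compute_weights(sched)
  expect_equal(sum(w), 1)
  expect_gt(w[sched$dur == 5][1], max(w[sched$dur == 0.5]))
  # lambda = 0 and equal durations -> uniform
  s2 <- make_frame_schedule(list(c(10, 2)))
  expect_equal(compute_weights(s2, decay_lambda = 0), rep(0.1, 10))
  expect_equal(compute_weights(sched, mode = "uniform"), rep(1 / 33, 33))
  expect_equal(sum(compute_weights(s2)), 1)
})

test_that("noise-free SRTM round trip recovers the generating parameters", {
  sched <- fx_sched(); ref <- fx_ref(); basis <- fx_basis()
  y <- srtm_forward(ref, sched, R1 = 1.0, k2 = 0.3, bp_nd = 2.5)
  fit <- fit_srtm(y, basis = basis)
  expect_lt(abs(fit$bp_nd - 2.5), 1e-3)
  expect_lt(abs(fit$R1 - 1.0), 1e-3)
  expect_lt(abs(fit$k2 - 0.3), 1e-3)
  expect_false(fit$boundary_flag)
  # invariant: BP = k2/k2a - 1 exactly as returned
  expect_equal(fit$bp_nd, fit$k2 / fit$k2a - 1)
})

test_that("fits through a reconstructed measured reference stay accurate", {
  sched <- fx_sched(); ref <- fx_ref()
  refI <- tac_to_fine(frame_average(ref, sched), sched)
  y <- srtm_forward(ref, sched, R1 = 1.0, k2 = 0.3, bp_nd = 2.5)
  fit <- fit_srtm(y, refI, sched)
  expect_lt(abs(fit$bp_nd - 2.5), 1e-3)
})

test_that("estimated BP is strictly ordered in the generating BP", {
  sched <- fx_sched(); ref <- fx_ref(); basis <- fx_basis()
  bps <- c(0.5, 1.5, 2.5)
  est <- vapply(bps, function(bp) {
    fit_srtm(srtm_forward(ref, sched, 1, 0.3, bp), basis = basis)$bp_nd
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("a target identical to the reference is reported as BP 0", {
  sched <- fx_sched(); ref <- fx_ref(); basis <- fx_basis()
  refF <- frame_average(ref, sched)
  fit <- fit_srtm(refF, basis = basis)
  expect_equal(fit$bp_nd, 0)
  expect_equal(fit$R1, 1, tolerance = 1e-8)
  expect_false(fit$boundary_flag)
})

test_that("degenerate inputs raise errors", {
  sched <- fx_sched(); basis <- fx_basis()
  expect_error(fit_srtm(c(1, 2), basis = basis), "frame count")
  bad <- rep(NA_real_, sched$n)
  expect_error(fit_srtm(bad, basis = basis), "finite")
  zero_ref <- fine_tac(seq(0, 120, 0.05), rep(0, 2401))
  y <- rep(1, sched$n)
  expect_error(fit_srtm(y, zero_ref, sched), "reference")
})

test_that("doubling the k2a grid density barely moves noise-free estimates", {
  sched <- fx_sched(); ref <- fx_ref()
  y <- srtm_forward(ref, sched, 1.1, 0.25, 1.8)
  f1 <- fit_srtm(y, ref, sched, k2a_grid = default_k2a_grid(128))
  f2 <- fit_srtm(y, ref, sched, k2a_grid = default_k2a_grid(256))
  expect_lt(abs(f1$bp_nd - f2$bp_nd) / f2$bp_nd, 0.005)
  # even the raw grid stage moves by less than the grid spacing
  g1 <- fit_srtm(y, ref, sched, refine = "none")
  g2 <- fit_srtm(y, ref, sched, k2a_grid = default_k2a_grid(256),
                 refine = "none")
  expect_lt(abs(g1$bp_nd - g2$bp_nd) / g2$bp_nd, 0.02)
})

test_that("BP estimates are approximately unbiased under default noise", {
  sched <- fx_sched(); ref <- fx_ref(); basis <- fx_basis()
  truth <- list(R1 = 1, k2 = 0.3, bp_nd = 2.5)
  est <- vapply(seq_len(200), function(s) {
    y <- simulate_target_tac(truth, ref, sched, noise_scale = 0.1, seed = s)
    fit_srtm(y, basis = basis, refine = "interp")$bp_nd
  }, numeric(1))
  expect_lt(abs(mean(est) - 2.5) / 2.5, 0.02)
})

test_that("tac container validates its inputs", {
  sched <- fx_sched()
  expect_error(tac(sched, rep(1, 5)), "number of frames")
  expect_error(tac(sched, rep(Inf, sched$n)), "finite")
  tt <- tac(sched, rep(1, sched$n), label = "x")
  expect_s3_class(tt, "tac")
})

test_that("tac_to_fine reproduces the measured frame averages", {
  sched <- fx_sched(); ref <- fx_ref()
  refF <- frame_average(ref, sched)
  fine <- tac_to_fine(refF, sched)
  expect_lt(max(abs(frame_average(fine, sched) - refF)), 1e-6 * max(refF))
})
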