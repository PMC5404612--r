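test_that("phantom volumes hit their targets within 10%", {
  ph <- fx_phantom()
  tgt <- default_phantom_volumes()
  expect_true(all(abs(ph$volumes_ml - tgt) / tgt < 0.10))
  # achieved volume is exactly count * voxel volume
  vox_ml <- prod(ph$voxel_size_mm) / 1000
  expect_equal(unname(ph$volumes_ml["putamen_l"]),
               sum(ph$labels == 3L) * vox_ml)
  # pooled putamen near the template 21.9 ml
  pooled <- ph$volumes_ml[["putamen_l"]] + ph$volumes_ml[["putamen_r"]]
  expect_lt(abs(pooled - 21.9) / 21.9, 0.10)
  expect_error(make_phantom(dims = c(16, 16, 8)), "fit|realise|overlap")
})

test_that("symmetric volume targets give mirror-equal caudate counts", {
  ph <- make_phantom(region_volumes = c(caudate_l = 10.2, caudate_r = 10.2))
  expect_equal(sum(ph$labels == 1L), sum(ph$labels == 2L))
})

test_that("noise-free rendering and extraction invert each other", {
  ph <- fx_phantom()
  sched <- fx_sched(); ref <- fx_ref()
  rt <- list(cerebellum = srtm_forward(ref, sched, 1, 0.3, 0))
  for (nm in setdiff(names(ph$label_map), c("background", "cerebellum"))) {
    rt[[nm]] <- srtm_forward(ref, sched, 1, 0.3, 2.5)
  }
  img <- render_dynamic_image(ph, rt, sched)
  for (nm in c("putamen_l", "cerebellum")) {
    expect_equal(extract_roi_tac(img, ph, nm)$activity, rt[[nm]])
  }
  # constant fill: whole-striatum pooling equals the shared TAC
  expect_equal(extract_roi_tac(img, ph, "striatum")$activity,
               rt$putamen_l)
  expect_error(render_dynamic_image(ph, rt[-2], sched), "missing TAC")
  expect_error(extract_roi_tac(img, ph, "bogus"), "unknown")
})

test_that("whole-striatum pooling is the voxel-count-weighted sub-region mean", {
  ph <- fx_phantom()
  sched <- fx_sched(); ref <- fx_ref()
  bps <- c(caudate_l = 2.4, caudate_r = 2.4, putamen_l = 2.8,
           putamen_r = 2.8, ventral_striatum_l = 2.2,
           ventral_striatum_r = 2.2)
  rt <- lapply(bps, function(b) srtm_forward(ref, sched, 1, 0.3, b))
  rt$cerebellum <- srtm_forward(ref, sched, 1, 0.3, 0)
  img <- render_dynamic_image(ph, rt, sched)
  pooled <- extract_roi_tac(img, ph, "striatum")$activity
  counts <- vapply(names(bps), function(nm)
    sum(ph$labels == ph$label_map[[nm]]), numeric(1))
  manual <- Reduce(`+`, Map(function(nm, n) n * rt[[nm]],
                            names(bps), counts)) / sum(counts)
  expect_equal(pooled, manual, tolerance = 1e-12)
})

test_that("rendering is seed-reproducible and ROI noise obeys the CLT", {
  ph <- fx_phantom()
  sched <- make_frame_schedule(list(c(4, 5)))  # short schedule for speed
  y <- rep(10, 4)
  rt <- lapply(setdiff(names(ph$label_map), "background"), function(nm) y)
  names(rt) <- setdiff(names(ph$label_map), "background")
  i1 <- render_dynamic_image(ph, rt, sched, voxel_noise_scale = 1, seed = 4)
  i2 <- render_dynamic_image(ph, rt, sched, voxel_noise_scale = 1, seed = 4)
  expect_identical(i1$data, i2$data)
  # ROI-mean noise SD shrinks like 1/sqrt(voxel count)
  roi_sd <- function(labels) {
    sd(vapply(1:50, function(s) {
      img <- render_dynamic_image(ph, rt, sched, voxel_noise_scale = 1,
                                  seed = s)
      extract_roi_tac(img, ph, labels)$activity[1]
    }, numeric(1)))
  }
  n_put <- sum(ph$labels %in% c(3L, 4L))
  n_vs <- sum(ph$labels %in% c(5L, 6L))
  ratio <- roi_sd("ventral_striatum") / roi_sd("putamen")
  expect_equal(ratio, sqrt(n_put / n_vs), tolerance = 0.25)
})

test_that("voxel fits on a homogeneous noise-free phantom equal the ROI fit", {
  ph <- fx_phantom()
  sched <- fx_sched(); ref <- fx_ref()
  rt <- list(cerebellum = srtm_forward(ref, sched, 1, 0.3, 0))
  for (nm in setdiff(names(ph$label_map), c("background", "cerebellum"))) {
    rt[[nm]] <- srtm_forward(ref, sched, 1, 0.3, 2.5)
  }
  img <- render_dynamic_image(ph, rt, sched)
  refI <- tac_to_fine(extract_roi_tac(img, ph, "cerebellum"), sched)
  vm <- fit_voxelwise(img, refI, ph, labels = "putamen_l")
  roi <- fit_srtm(extract_roi_tac(img, ph, "putamen_l"), refI, sched,
                  refine = "interp")
  vals <- vm$bp[!is.na(vm$bp)]
  expect_gt(length(vals), 100)
  expect_lt(max(abs(vals - roi$bp_nd)), 1e-9)
  expect_lt(abs(roi$bp_nd - 2.5), 1e-3)
})

test_that("degenerate voxels are marked invalid, not propagated", {
  ph <- fx_phantom()
  sched <- fx_sched(); ref <- fx_ref()
  rt <- list(cerebellum = srtm_forward(ref, sched, 1, 0.3, 0))
  for (nm in setdiff(names(ph$label_map), c("background", "cerebellum"))) {
    rt[[nm]] <- srtm_forward(ref, sched, 1, 0.3, 2.0)
  }
  img <- render_dynamic_image(ph, rt, sched)
  # zero out one putamen voxel's time course
  idx <- which(ph$labels == 3L)[1]
  nvox <- prod(dim(ph$labels))
  for (f in seq_len(sched$n)) img$data[idx + (f - 1L) * nvox] <- 0
  refI <- tac_to_fine(extract_roi_tac(img, ph, "cerebellum"), sched)
  vm <- fit_voxelwise(img, refI, ph, labels = "putamen_l")
  expect_false(vm$valid[idx])
  expect_true(is.na(vm$bp[idx]))
  s <- summarize_bp_map(vm, ph, "putamen")
  expect_true(is.finite(s$mean_bp))
})
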