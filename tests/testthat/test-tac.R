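test_that("recovery correction follows its definition and is linear", {
  expect_equal(recovery_correct(5, 100, 100), 5)          # recovery 1
  expect_equal(recovery_correct(9, 90, 100), 10)          # recovery 0.9
  expect_equal(recovery_correct(2 * 9, 90, 100), 2 * 10)  # linearity
  expect_error(recovery_correct(1, 0, 100), "> 0")
  expect_error(recovery_correct(1, 10, 0), "> 0")
  expect_warning(recovery_correct(1, 110, 100), "calibration drift")
})

test_that("to_tac stamps bed midtimes, undecays and normalises", {
  sch <- default_schedule()
  nuc <- nuclide_f18()
  meas <- data.frame(organ = rep(c("thyroid", "esophagus"), each = 8),
                     frame = rep(1:8, 2),
                     activity = rep(c(2, 1), each = 8))
  beds <- list(thyroid = 1L, esophagus = 2:3)
  tacs <- to_tac(meas, sch, injected_activity = 100, nuc, organ_beds = beds)
  expect_s3_class(tacs, "organ_tacs")
  expect_equal(nrow(tacs), 16L)
  thy <- organ_tac(tacs, "thyroid")
  expect_equal(nrow(thy), 8L)
  expect_false(is.unsorted(thy$time_h, strictly = TRUE))
  expect_equal(thy$time_h[3], organ_midtime(sch, 3, 1L))
  expect_equal(thy$fraction_id_dc, rep(0.02, 8))
  expect_equal(thy$fraction_id,
               0.02 * exp(-nuc$decay_constant_h * thy$time_h))
  # spanning organ is stamped at the midpoint of its beds' midtimes
  eso <- organ_tac(tacs, "esophagus")
  expect_equal(eso$time_h[1], organ_midtime(sch, 1, 2:3))
  # invariant to input row order
  tacs2 <- to_tac(meas[rev(seq_len(16)), ], sch, 100, nuc, organ_beds = beds)
  expect_equal(tacs2, tacs)
  expect_error(to_tac(data.frame(organ = "x", frame = 9, activity = 1),
                      sch, 100, nuc), "outside the schedule")
})

test_that("frame-dependent recovery losses are corrected exactly", {
  recov <- c(0.80, 0.85, 0.90, 0.92, 0.95, 0.97, 0.99, 1.00)
  ph <- make_phantom(noise_sd = 0, recovery = recov)
  ds <- sample_biodistribution(ph, default_schedule(), seed = 1)
  tacs <- tacs_from_dataset(ds)
  for (org in c("stomach", "lungs", "thyroid")) {
    tac <- organ_tac(tacs, org)
    expect_equal(tac$fraction_id_dc,
                 fraction_at(ph$organ_models[[org]], tac$time_h),
                 tolerance = 1e-12)
  }
})

test_that("whole-body activity undecays to the physical decay curve", {
  ph <- make_phantom(noise_sd = 0)
  ds <- sample_biodistribution(ph, default_schedule(), seed = 1)
  nuc <- ph$nuclide
  # whole-body VOI is decay-corrected: constant at the injected activity
  expect_equal(ds$wholebody$activity_mbq, rep(ph$injected_mbq, 8))
  t_h <- bed_midtimes(default_schedule())$midtime_h[seq(3, 40, by = 5)]
  expect_equal(undecay_to_midtime(ds$wholebody$activity_mbq, t_h, nuc),
               ph$injected_mbq * exp(-nuc$decay_constant_h * t_h))
})

test_that("voi_total sums labelled voxels", {
  vol <- array(2, c(4, 4, 4))
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, 1, 1] <- 5L
  expect_equal(voi_total(vol, lab, 5L, voxel_volume_ml = 0.5), 2 * 2 * 0.5)
  expect_error(voi_total(vol, lab, 7L, 0.5), "not present")
  expect_error(voi_total(vol, array(0L, c(2, 2, 2)), 5L, 0.5), "dimensions")
})

test_that("ellipsoid phantom VOI totals match generator bookkeeping", {
  organs <- data.frame(label = c(1L, 2L),
                       cx = c(40, 80), cy = c(60, 60), cz = c(60, 60),
                       rx = c(22, 14), ry = c(18, 12), rz = c(20, 16),
                       activity = c(37, 11))
  vx <- make_voxel_phantom(organs, dim_xyz = c(48L, 48L, 48L), voxel_mm = 2.6)
  for (i in 1:2) {
    expect_equal(voi_total(vx$volume, vx$labels, organs$label[i],
                           vx$voxel_volume_ml),
                 organs$activity[i], tolerance = 0.01)
  }
})
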