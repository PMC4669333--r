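test_that("default schedule reproduces the 8-frame protocol", {
  sch <- default_schedule()
  expect_length(sch$frame_starts_min, 8L)
  expect_equal(sch$frame_starts_min[8], 106)
  expect_equal(sch$bed_durations_s[8], 300)
  expect_equal(sch$beds_per_frame, 5L)
  # emission ends at 106 min + 5 x 300 s + 4 x 12 s = 131.8 min
  expect_equal(emission_end(sch), 131.8, tolerance = 1e-12)
  expect_true(emission_end(sch) >= 131 && emission_end(sch) <= 132)
})

test_that("degenerate and invalid schedules are handled", {
  one <- scan_schedule(0, 10, beds_per_frame = 1L)
  expect_equal(emission_end(one), 10 / 60)
  expect_equal(bed_midtimes(one)$midtime_min, 5 / 60)
  expect_error(scan_schedule(c(0, 5, 3), c(10, 10, 10)), "strictly increasing")
  expect_error(scan_schedule(c(0, 1), c(120, 120)), "overlap")
  expect_error(scan_schedule(c(0, 5), c(10, -1)), "positive")
})

test_that("bed midtimes follow the bed arithmetic and are monotone", {
  sch <- default_schedule()
  mt <- bed_midtimes(sch)
  expect_equal(nrow(mt), 40L)
  # frame 1 (start 0, 15 s beds): bed 1 midtime 7.5 s
  expect_equal(mt$midtime_min[mt$frame == 1 & mt$bed == 1], 7.5 / 60)
  # frame 2 (start 3.5 min, 60 s beds): bed 3 starts at 354 s, mid 384 s
  expect_equal(mt$start_min[mt$frame == 2 & mt$bed == 3], 354 / 60)
  expect_equal(mt$midtime_min[mt$frame == 2 & mt$bed == 3], 384 / 60)
  expect_false(is.unsorted(mt$midtime_min, strictly = TRUE))
  # each midtime lies inside its frame
  ends <- sch$frame_end_min[mt$frame]
  starts <- sch$frame_starts_min[mt$frame]
  expect_true(all(mt$midtime_min > starts & mt$midtime_min < ends))
})

test_that("midtimes are monotone for a perturbed but valid schedule", {
  sch <- scan_schedule(c(0, 4, 9, 30), c(20, 30, 60, 200),
                       beds_per_frame = 3L, inter_bed_gap_s = 7)
  expect_false(is.unsorted(bed_midtimes(sch)$midtime_min, strictly = TRUE))
})

test_that("organ midtime for spanned beds is the midpoint of bed midtimes", {
  sch <- default_schedule()
  mt <- bed_midtimes(sch)
  m2 <- mt$midtime_h[mt$frame == 3 & mt$bed == 2]
  m3 <- mt$midtime_h[mt$frame == 3 & mt$bed == 3]
  expect_equal(organ_midtime(sch, 3, 2:3), (m2 + m3) / 2)
  expect_error(organ_midtime(sch, 9, 1), "outside the schedule")
})

test_that("undecay reverses the reconstruction decay correction", {
  nuc <- nuclide_f18()
  expect_equal(undecay_to_midtime(1, 0, nuc), 1)
  expect_equal(undecay_to_midtime(1, nuc$half_life_h, nuc), 0.5)
  # round trip is the identity to machine precision
  t <- c(0.1, 0.5, 1.9)
  a <- c(3, 7, 0.2)
  expect_equal(decay_correct(undecay_to_midtime(a, t, nuc), t, nuc), a)
  expect_error(undecay_to_midtime(-1, 0.5, nuc), "non-negative")
})
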