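test_that("trapezoid + physical tail reproduces hand-checked values", {
  nuc183 <- nuclide("F-18 (rounded)", half_life_h = 1.83,
                    positron_yield = 0.967, mean_beta_energy_mev = 0.2498)
  # {(0,0),(1 h,0.10)}: trapezoid 0.05, tail 0.10 * 1.83/ln2 -> 0.314013 h
  tac <- data.frame(time_h = c(0, 1), fraction_id = c(0, 0.10))
  expect_equal(residence_trapezoid_tail(tac, nuc183), 0.314013,
               tolerance = 1e-5)
  # all-zero TAC -> 0
  z <- data.frame(time_h = 1:5, fraction_id = 0)
  expect_equal(residence_trapezoid_tail(z, nuc183), 0)
  # dense sampling of a purely physical decay curve -> f / lambda_p
  nuc <- nuclide_f18()
  t <- seq(0, 12, by = 0.02)
  dense <- data.frame(time_h = t,
                      fraction_id = 0.3 * exp(-nuc$decay_constant_h * t))
  expect_equal(residence_trapezoid_tail(dense, nuc),
               0.3 / nuc$decay_constant_h, tolerance = 0.005)
  expect_error(residence_trapezoid_tail(dense[0, ], nuc), "no points")
  expect_error(residence_trapezoid_tail(
    data.frame(time_h = 1, fraction_id = -1), nuc), "non-negative")
})

test_that("trapezoid residence is monotone in the TAC values", {
  nuc <- nuclide_f18()
  set.seed(42)
  for (i in 1:20) {
    t <- sort(runif(6, 0.01, 2))
    v <- runif(6, 0, 0.2)
    base <- residence_trapezoid_tail(data.frame(time_h = t, fraction_id = v), nuc)
    j <- sample.int(6, 1)
    v2 <- v; v2[j] <- v2[j] + runif(1, 0, 0.1)
    up <- residence_trapezoid_tail(data.frame(time_h = t, fraction_id = v2), nuc)
    expect_gte(up, base)
  }
})

test_that("blood residence converts per-gram curves and integrates", {
  nuc <- nuclide_f18()
  lp <- nuc$decay_constant_h
  hc <- hematologic_constants()
  # per-gram value c over 70 kg -> whole-blood fraction c * 3780
  expect_equal(hc$blood_mass_fraction * 70 * 1000, 3780)
  # constant decay-corrected whole-blood fraction f -> f / lambda_p
  t <- seq(0, 2.2, by = 0.05)
  f <- 0.30
  curve <- data.frame(time_h = t,
                      fraction_id_per_g = f * exp(-lp * t) / 3780)
  expect_equal(blood_residence(curve, 70, hc, nuc), f / lp, tolerance = 0.01)
  # synthetic declining blood model vs the quadrature oracle
  ph <- make_phantom(noise_sd = 0)
  bl <- sample_blood(ph, seed = 1)
  tau_hat <- blood_residence(bl, ph$body_mass_kg, hc, nuc)
  tau_true <- quad_residence(function(t) fraction_at(ph$blood_model, t), nuc)
  expect_equal(tau_hat, tau_true, tolerance = 0.05)
  expect_error(blood_residence(curve, -1, hc, nuc), "positive")
  expect_error(blood_residence(curve[1, , drop = FALSE], 70, hc, nuc),
               "at least 2")
})

test_that("blood-derived organ shares follow the hematologic rules", {
  hc <- hematologic_constants()
  expect_equal(red_marrow_residence(1, hc), 0.19 / (1 - 0.39))
  expect_equal(red_marrow_residence(0, hc), 0)
  expect_equal(spleen_residence(1, hc), 0.015)
  # consistency with the bundled reference table, by inversion
  blood_tau <- ref_taus()[["red_marrow"]] * (1 - 0.39) / 0.19
  expect_equal(blood_tau, 0.2777, tolerance = 0.001)
  expect_equal(spleen_residence(blood_tau, hc), ref_taus()[["spleen"]],
               tolerance = 0.01)
  # spleen/marrow ratio is a fixed algebraic identity
  expect_equal(spleen_residence(2.5, hc) / red_marrow_residence(2.5, hc),
               0.015 * (1 - 0.39) / 0.19)
  expect_error(red_marrow_residence(-1, hc), "non-negative")
  expect_error(hematologic_constants(marrow_numerator = 1.2), "in \\(0, 1\\)")
})

test_that("remainder closes the residence-time budget", {
  nuc <- nuclide_f18()
  expect_equal(remainder_residence(numeric(0), nuc), 2.635, tolerance = 0.005)
  taus <- ref_taus()
  measured <- taus[names(taus) != "remainder"]
  expect_equal(remainder_residence(measured, nuc), taus[["remainder"]],
               tolerance = 0.01)
  expect_error(remainder_residence(c(a = 2, b = 1), nuc), "exceeding")
  # conservation after assembly, to 1e-9
  rs <- residence_time_set(measured, nuc)
  expect_equal(sum(rs$entries) + rs$remainder, max_residence_time(nuc),
               tolerance = 1e-9)
  expect_equal(as.data.frame(rs)$tau_h,
               c(unname(measured), rs$remainder))
})
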