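test_that("default phantom carries the twelve source organs and blood", {
  ph <- make_phantom()
  expect_setequal(names(ph$organ_models),
                  c("lungs", "brain", "heart_contents", "kidneys", "stomach",
                    "urinary_bladder", "thyroid", "olfactory_mucosa",
                    "esophagus", "parotid_gland", "sublingual_gland",
                    "submandibular_gland"))
  expect_s3_class(ph$blood_model, "organ_model")
  expect_error(make_phantom(organ_models = list()), "empty")
})

test_that("phantom validation rejects over-unity fractions", {
  too_hot <- list(a = organ_model("a", "constant_fraction", F = 0.7),
                  b = organ_model("b", "constant_fraction", F = 0.5))
  expect_error(make_phantom(organ_models = too_hot), "exceed 1")
  expect_error(organ_model("x", "biexp_washout", A1 = -0.1), "non-negative")
  expect_error(organ_model("x", "uptake_to_plateau", F = 0.1, lambda = -2),
               "non-negative")
})

test_that("analytic residence matches closed forms and quadrature", {
  nuc <- nuclide_f18()
  lp <- nuc$decay_constant_h
  const <- organ_model("x", "constant_fraction", F = 0.02)
  expect_equal(analytic_residence(const, nuc), 0.02 / lp)
  mono <- organ_model("x", "biexp_washout", A1 = 0.1, lambda1 = 1.7)
  expect_equal(analytic_residence(mono, nuc), 0.1 / (1.7 + lp))
  # bi-exponential and uptake forms against adaptive quadrature
  for (mod in list(
    organ_model("x", "biexp_washout", A1 = 0.08, lambda1 = 5.2,
                A2 = 0.02, lambda2 = 0.9),
    organ_model("x", "uptake_to_plateau", F = 0.2, lambda = 2.1),
    organ_model("x", "cumulative_bladder", F = 0.25, lambda = 1.4))) {
    expect_equal(analytic_residence(mod, nuc),
                 quad_residence(function(t) fraction_at(mod, t), nuc),
                 tolerance = 1e-6)
  }
})

test_that("noise-free sampling returns exact model values and is reproducible", {
  ph <- make_phantom(noise_sd = 0)
  sch <- default_schedule()
  ds <- sample_biodistribution(ph, sch, seed = 7)
  # organ activity equals the decay-corrected model value at the midtime
  row <- ds$organ_table[ds$organ_table$organ == "stomach" &
                          ds$organ_table$frame == 5, ]
  mod <- ph$organ_models$stomach
  expect_equal(row$activity_mbq,
               fraction_at(mod, row$midtime_min / 60) * ph$injected_mbq)
  # thyroid decay-corrected TAC is flat across frames
  thy <- ds$organ_table[ds$organ_table$organ == "thyroid", "activity_mbq"]
  expect_equal(diff(range(thy)), 0)
  # determinism: identical seeds give bit-identical datasets
  ph_n <- make_phantom(noise_sd = 0.05)
  d1 <- sample_biodistribution(ph_n, sch, seed = 11)
  d2 <- sample_biodistribution(ph_n, sch, seed = 11)
  expect_identical(d1$organ_table, d2$organ_table)
  expect_identical(d1$wholebody, d2$wholebody)
  d3 <- sample_biodistribution(ph_n, sch, seed = 12)
  expect_false(identical(d1$organ_table, d3$organ_table))
})

test_that("multiplicative noise has the configured relative SD", {
  ph <- make_phantom(noise_sd = 0.05)
  sch <- default_schedule()
  vals <- vapply(1:100, function(s) {
    ds <- sample_biodistribution(ph, sch, seed = s)
    ds$organ_table$activity_mbq[ds$organ_table$organ == "thyroid" &
                                  ds$organ_table$frame == 4]
  }, numeric(1))
  cv <- stats::sd(vals) / mean(vals)
  # sd of a sample CV at n = 100 is roughly cv / sqrt(2 n) ~ 0.0035
  expect_gt(cv, 0.05 - 3 * 0.0035)
  expect_lt(cv, 0.05 + 3 * 0.0035)
})

test_that("blood sampling matches the stated draw protocol", {
  ph <- make_phantom()
  bl <- sample_blood(ph, seed = 3)
  expect_equal(nrow(bl), 10L)
  expect_equal(bl$fraction_id_per_g[bl$time_min == 0], 0)
  post <- bl$fraction_id_per_g[bl$time_min > 0]
  expect_false(is.unsorted(rev(post), strictly = TRUE))  # strictly decreasing
  expect_error(sample_blood(ph, draw_times_min = c(-1, 5)), "non-negative")
})

test_that("instantaneous organ + blood fraction never exceeds one", {
  ph <- make_phantom()
  grid <- seq(0, 4, by = 0.01)
  tot <- rowSums(vapply(c(ph$organ_models, list(ph$blood_model)),
                        fraction_at, numeric(length(grid)), time_h = grid))
  expect_lte(max(tot), 1)
})
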