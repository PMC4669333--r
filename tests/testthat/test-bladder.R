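frame_times_h <- function() {
  mt <- bed_midtimes(default_schedule())
  mt$midtime_h[mt$bed == 4]
}

test_that("increase-to-maximum fit recovers noiseless parameters", {
  t <- frame_times_h()
  F_true <- 0.3
  lb_true <- log(2) / 0.5
  tac <- data.frame(time_h = t, fraction_id_dc = F_true * (1 - exp(-lb_true * t)))
  fit <- fit_bladder(tac)
  expect_equal(fit$plateau_fraction, F_true, tolerance = 1e-6)
  expect_equal(fit$biologic_rate, lb_true, tolerance = 1e-6)
  expect_equal(fit$flag, "ok")
  expect_lt(fit$residual_norm, 1e-6)
})

test_that("degenerate bladder TACs are flagged or rejected", {
  t <- frame_times_h()
  z <- data.frame(time_h = t, fraction_id_dc = rep(0, length(t)))
  fit <- fit_bladder(z)
  expect_equal(fit$plateau_fraction, 0)
  expect_equal(fit$flag, "unidentifiable")
  expect_error(fit_bladder(z[1:2, ]), "at least 3")
  expect_warning(
    fit_bladder(data.frame(time_h = t,
                           fraction_id_dc = rev(0.1 * (1 - exp(-2 * t))))),
    "decreasing")
})

test_that("fit is accurate under measurement noise (Monte Carlo)", {
  t <- frame_times_h()
  F_true <- 0.25
  lb_true <- log(2) / 0.5
  clean <- F_true * (1 - exp(-lb_true * t))
  set.seed(2024)
  f_hat <- replicate(200, {
    noisy <- clean * exp(rnorm(length(t), 0, sqrt(log(1 + 0.05^2))))
    fit_bladder(data.frame(time_h = t, fraction_id_dc = noisy))$plateau_fraction
  })
  expect_lt(abs(stats::median(f_hat) / F_true - 1), 0.02)
})

test_that("voiding-model residence matches limits and the stepping oracle", {
  nuc <- nuclide_f18()
  lp <- nuc$decay_constant_h
  mk <- function(F, lb) list(plateau_fraction = F, biologic_rate = lb)
  expect_equal(bladder_residence_voiding(mk(0, 2), nuc, 2.4), 0)
  # instantaneous filling with no voiding: tau -> 1 / lambda_p
  expect_equal(bladder_residence_voiding(mk(1, Inf), nuc, 1e6),
               1 / lp, tolerance = 1e-6)
  # no voiding recovers the closed form F lb / ((lb + lp) lp)
  expect_equal(bladder_residence_voiding(mk(0.4, 1.3), nuc, 1e5),
               0.4 * 1.3 / ((1.3 + lp) * lp), tolerance = 1e-9)
  # against the dt = 0.1 s explicit time-stepping oracle
  lb <- log(2) / 0.5
  tau <- bladder_residence_voiding(mk(1, lb), nuc, 2.4)
  expect_equal(tau, bladder_tau_oracle(1, lb, nuc, 2.4), tolerance = 1e-3)
  expect_error(bladder_residence_voiding(mk(0.5, 2), nuc, 0), "> 0")
})

test_that("voiding residence decreases with shorter voiding intervals", {
  nuc <- nuclide_f18()
  fit <- list(plateau_fraction = 0.3, biologic_rate = 1.4)
  tv <- c(0.3, 0.6, 1.2, 2.4, 4.8, 24)
  taus <- vapply(tv, function(v) bladder_residence_voiding(fit, nuc, v),
                 numeric(1))
  expect_false(is.unsorted(taus, strictly = TRUE))
})
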