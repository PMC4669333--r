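# Independent numerical oracles used to freeze expected values.

# adaptive-quadrature residence time of a decay-corrected fraction curve
quad_residence <- function(fdc, nuclide = nuclide_f18(), upper = Inf) {
  lp <- nuclide$decay_constant_h
  stats::integrate(function(t) fdc(t) * exp(-lp * t), 0, upper,
                   rel.tol = 1e-10, abs.tol = 0)$value
}

# brute-force time-stepped dynamic-bladder simulation (explicit Euler with
# a C-level recursive filter); independent of the closed-form implementation
bladder_tau_oracle <- function(F, lambda_b, nuclide = nuclide_f18(),
                               voiding_interval_h = 2.4, dt_s = 0.1,
                               horizon_h = 40) {
  lp <- nuclide$decay_constant_h
  dt <- dt_s / 3600
  tau <- 0
  k <- 0
  while (k * voiding_interval_h < horizon_h) {
    t <- seq(k * voiding_interval_h, (k + 1) * voiding_interval_h - dt, by = dt)
    inflow <- F * lambda_b * exp(-(lambda_b + lp) * t) * dt
    content <- stats::filter(inflow, 1 - lp * dt, method = "recursive")
    tau <- tau + sum(content) * dt
    k <- k + 1
  }
  tau
}

# explicit double-loop MIRD sum, oracle for the matrix product
organ_doses_oracle <- function(taus, S) {
  out <- numeric(length(S$targets))
  names(out) <- S$targets
  for (tgt in S$targets) {
    acc <- 0
    for (src in names(taus)) acc <- acc + taus[[src]] * S$values[tgt, src]
    out[tgt] <- acc
  }
  out
}

ref_taus <- function() {
  df <- reference_residence_times()
  stats::setNames(df$tau_h, df$organ)
}

ref_doses <- function() {
  df <- reference_organ_doses()
  stats::setNames(df$dose_mgy_per_mbq, df$organ)
}
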