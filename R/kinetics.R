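#' Hematologic constants for blood-derived residence times
#'
#' Red-marrow share `0.19 / (1 - 0.39)` of the blood residence time
#' (marrow blood fraction over one minus hematocrit), spleen share 1.5 %
#' of the blood residence time, and blood mass as 5.4 % of body mass.
#'
#' @param marrow_numerator,marrow_complement Constants of the red-marrow
#'   rule `tau_rm = marrow_numerator / (1 - marrow_complement) * tau_blood`.
#' @param spleen_blood_fraction Spleen share of the blood residence time.
#' @param blood_mass_fraction Blood mass as a fraction of body mass.
#' @return List of the four constants.
#' @export
hematologic_constants <- function(marrow_numerator = 0.19,
                                  marrow_complement = 0.39,
                                  spleen_blood_fraction = 0.015,
                                  blood_mass_fraction = 0.054) {
  vals <- c(marrow_numerator, marrow_complement, spleen_blood_fraction,
            blood_mass_fraction)
  if (any(vals <= 0) || any(vals >= 1))
    stop("all hematologic constants must lie in (0, 1)")
  list(marrow_numerator = marrow_numerator,
       marrow_complement = marrow_complement,
       spleen_blood_fraction = spleen_blood_fraction,
       blood_mass_fraction = blood_mass_fraction)
}

#' Residence time by trapezoid integration with a physical-decay tail
#'
#' Integrates a fraction-of-injected-dose TAC (physical fractions, i.e.
#' with decay included) by the trapezoid rule from injection to the last
#' measurement, prepending a (0, 0) point when the curve does not start at
#' t = 0, then adds the tail `last_value / lambda_p` under the assumption
#' that all clearance after the last point is physical decay only — a
#' deliberately conservative extrapolation.
#'
#' @param tac data.frame with columns `time_h` and `fraction_id`
#'   (physical fraction of injected activity), times strictly increasing.
#' @param nuclide A [nuclide] object.
#' @return Residence time in hours.
#' @export
residence_trapezoid_tail <- function(tac, nuclide = nuclide_f18()) {
  nuclide <- as_nuclide(nuclide)
  stopifnot(is.data.frame(tac), all(c("time_h", "fraction_id") %in% names(tac)))
  if (nrow(tac) == 0L) stop("TAC has no points")
  t <- tac$time_h
  v <- tac$fraction_id
  if (any(v < 0)) stop("TAC values must be non-negative")
  if (is.unsorted(t, strictly = TRUE)) stop("TAC times must be strictly increasing")
  if (t[1] > 0) { t <- c(0, t); v <- c(0, v) }
  trap <- sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  trap + v[length(v)] / nuclide$decay_constant_h
}

#' Fit an increase-to-maximum curve to a decay-corrected bladder TAC
#'
#' Least-squares fit of `F (1 - exp(-lambda_b t))` to the decay-corrected
#' cumulative bladder curve. `F` is the fraction of injected activity
#' cleared into urine (the plateau) and `lambda_b` the biologic filling
#' rate (urinary biologic half-life `log(2) / lambda_b`). The fit profiles
#' `F` out analytically (linear in `F` given `lambda_b`) and optimises the
#' one-dimensional profile, which is robust and recovers noise-free curves
#' to machine-level accuracy.
#'
#' @param tac data.frame with columns `time_h` and either `fraction_id_dc`
#'   or `value` (decay-corrected fractions of injected activity).
#' @param rate_interval Search interval for `lambda_b` (1/h).
#' @return An object of class `bladder_fit`: list with `plateau_fraction`,
#'   `biologic_rate` (1/h), `biologic_half_life_h`, `residual_norm`, and
#'   `flag` (`"ok"` or `"unidentifiable"`).
#' @export
fit_bladder <- function(tac, rate_interval = c(1e-4, 200)) {
  stopifnot(is.data.frame(tac), "time_h" %in% names(tac))
  y <- if ("fraction_id_dc" %in% names(tac)) tac$fraction_id_dc else tac$value
  if (is.null(y)) stop("need a 'fraction_id_dc' or 'value' column")
  t <- tac$time_h
  keep <- t > 0
  t <- t[keep]; y <- y[keep]
  if (length(t) < 3L) stop("bladder fit needs at least 3 post-injection points")
  if (any(y < 0)) stop("decay-corrected bladder TAC must be non-negative")
  if (all(y == 0)) {
    return(structure(list(plateau_fraction = 0, biologic_rate = NA_real_,
                          biologic_half_life_h = NA_real_,
                          residual_norm = 0, flag = "unidentifiable"),
                     class = "bladder_fit"))
  }
  if (stats::cor(t, y) < 0)
    warning("bladder TAC trend is decreasing; increase-to-maximum fit is suspect")
  prof <- function(lb) {
    g <- 1 - exp(-lb * t)
    f <- sum(y * g) / sum(g * g)
    sum((y - f * g)^2)
  }
  opt <- stats::optimize(prof, interval = rate_interval, tol = 1e-12)
  lb <- opt$minimum
  g <- 1 - exp(-lb * t)
  f <- sum(y * g) / sum(g * g)
  structure(list(plateau_fraction = f, biologic_rate = lb,
                 biologic_half_life_h = log(2) / lb,
                 residual_norm = sqrt(opt$objective), flag = "ok"),
            class = "bladder_fit")
}

#' @export
print.bladder_fit <- function(x, ...) {
  cat(sprintf("<bladder_fit> F = %.4g, lambda_b = %.4g /h (T1/2,biol = %.3g h), resid %.3g [%s]\n",
              x$plateau_fraction, x$biologic_rate, x$biologic_half_life_h,
              x$residual_norm, x$flag))
  invisible(x)
}

#' Bladder residence time under a dynamic voiding model
#'
#' Urine flows into the bladder at the biologic rate
#' `F lambda_b exp(-lambda_b t)` (so the physical inflow rate is
#' `F lambda_b exp(-(lambda_b + lambda_p) t)`), the content decays
#' physically between voids, and the bladder is emptied at every multiple
#' of the voiding interval. Within the k-th interval the physical content is
#' `A(t) = F exp(-lambda_p t) (exp(-lambda_b t_k) - exp(-lambda_b t))`,
#' which integrates in closed form; intervals are summed until the added
#' term falls below 1e-12.
#'
#' @param fit A [fit_bladder()] result, or a list with `plateau_fraction`
#'   and `biologic_rate`.
#' @param nuclide A [nuclide] object.
#' @param voiding_interval_h Time between voids (h); default 2.4.
#' @return Residence time of the bladder contents in hours.
#' @export
bladder_residence_voiding <- function(fit, nuclide = nuclide_f18(),
                                      voiding_interval_h = 2.4) {
  nuclide <- as_nuclide(nuclide)
  if (voiding_interval_h <= 0) stop("voiding_interval_h must be > 0")
  f <- fit$plateau_fraction
  lb <- fit$biologic_rate
  lp <- nuclide$decay_constant_h
  if (f < 0 || f > 1) stop("plateau fraction must lie in [0, 1]")
  if (f == 0) return(0)
  if (is.na(lb) || lb < 0) stop("biologic rate is not available")
  if (lb == 0) return(0)  # no urine inflow
  tv <- voiding_interval_h
  tau <- 0
  k <- 0
  repeat {
    t0 <- k * tv; t1 <- t0 + tv
    # integral of exp(-lambda t) over [t0, t1], stable for lambda -> Inf
    int_p <- (exp(-lp * t0) - exp(-lp * t1)) / lp
    lbp <- lb + lp
    int_bp <- if (is.infinite(lbp)) 0 else (exp(-lbp * t0) - exp(-lbp * t1)) / lbp
    ebt0 <- if (t0 == 0) 1 else exp(-lb * t0)  # exp(-Inf * 0) would be NaN
    term <- f * (ebt0 * int_p - int_bp)
    tau <- tau + term
    k <- k + 1
    if (term < 1e-12 || k > 100000L) break
  }
  tau
}

#' Whole-blood residence time from a sampled blood curve
#'
#' Converts a per-gram blood curve (physical fraction of injected activity
#' per gram) into a whole-blood TAC by multiplying by the blood mass
#' (`blood_mass_fraction * body mass`), then integrates with
#' [residence_trapezoid_tail()]. Returns the total blood residence time,
#' before any share is assigned to spleen or red marrow.
#'
#' @param blood_curve data.frame with `time_h` (or `time_min`) and
#'   `fraction_id_per_g`.
#' @param body_mass_kg Body mass in kg.
#' @param constants [hematologic_constants()].
#' @param nuclide A [nuclide] object.
#' @return Blood residence time in hours.
#' @export
blood_residence <- function(blood_curve, body_mass_kg,
                            constants = hematologic_constants(),
                            nuclide = nuclide_f18()) {
  stopifnot(is.data.frame(blood_curve),
            "fraction_id_per_g" %in% names(blood_curve))
  if (body_mass_kg <= 0) stop("body_mass_kg must be positive")
  if (nrow(blood_curve) < 2L) stop("blood curve needs at least 2 points")
  time_h <- if ("time_h" %in% names(blood_curve)) blood_curve$time_h
            else blood_curve$time_min / 60
  blood_g <- constants$blood_mass_fraction * body_mass_kg * 1000
  tac <- data.frame(time_h = time_h,
                    fraction_id = blood_curve$fraction_id_per_g * blood_g)
  residence_trapezoid_tail(tac, nuclide)
}

#' Red-marrow residence time from the blood residence time
#'
#' `tau_rm = 0.19 / (1 - 0.39) * tau_blood`: the marrow blood content as a
#' hematocrit-corrected fraction of the circulating blood.
#'
#' @param blood_tau Blood residence time (h), >= 0.
#' @param constants [hematologic_constants()].
#' @return Red-marrow residence time (h).
#' @export
red_marrow_residence <- function(blood_tau,
                                 constants = hematologic_constants()) {
  if (blood_tau < 0) stop("blood_tau must be non-negative")
  constants$marrow_numerator / (1 - constants$marrow_complement) * blood_tau
}

#' Spleen residence time from the blood residence time
#'
#' The spleen holds 1.5 % of the blood residence time.
#'
#' @inheritParams red_marrow_residence
#' @return Spleen residence time (h).
#' @export
spleen_residence <- function(blood_tau,
                             constants = hematologic_constants()) {
  if (blood_tau < 0) stop("blood_tau must be non-negative")
  constants$spleen_blood_fraction * blood_tau
}

#' Remainder-of-body residence time
#'
#' The theoretical total residence time `T1/2 / log(2)` minus the sum of
#' all explicitly measured source-organ residence times. A negative
#' remainder indicates over-accounted organs and is an error.
#'
#' @param entries Named numeric vector of organ residence times (h).
#' @param nuclide A [nuclide] object.
#' @return Remainder residence time (h).
#' @export
remainder_residence <- function(entries, nuclide = nuclide_f18()) {
  nuclide <- as_nuclide(nuclide)
  if (length(entries) && any(entries < 0))
    stop("residence times must be non-negative")
  rem <- max_residence_time(nuclide) - sum(entries)
  if (rem < 0)
    stop(sprintf("organ residence times sum to %.4g h, exceeding T1/2/ln2 = %.4g h",
                 sum(entries), max_residence_time(nuclide)))
  rem
}

#' Assemble a residence-time set with its remainder
#'
#' @param entries Named numeric vector of source-organ residence times (h).
#' @param nuclide A [nuclide] object.
#' @param method Named list of method flags recorded as metadata (e.g.
#'   bladder mode, recovery mode).
#' @return Object of class `residence_set`: list with `entries`,
#'   `remainder`, `nuclide`, `method`. By construction
#'   `sum(entries) + remainder == T1/2 / log(2)`.
#' @export
residence_time_set <- function(entries, nuclide = nuclide_f18(),
                               method = list()) {
  rem <- remainder_residence(entries, nuclide)
  structure(list(entries = entries, remainder = rem, nuclide = nuclide,
                 method = method), class = "residence_set")
}

#' @export
print.residence_set <- function(x, ...) {
  cat("<residence_set> (h)\n")
  df <- data.frame(organ = c(names(x$entries), "remainder"),
                   tau_h = signif(c(unname(x$entries), x$remainder), 4))
  print(df, row.names = FALSE)
  cat(sprintf("total %.6g h = T1/2/ln2\n", sum(x$entries) + x$remainder))
  invisible(x)
}

#' @export
as.data.frame.residence_set <- function(x, ...) {
  data.frame(organ = c(names(x$entries), "remainder"),
             tau_h = c(unname(x$entries), x$remainder))
}
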