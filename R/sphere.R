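# energy-to-dose conversion: MeV per decay -> mGy * g per MBq * h
# (1e6 decays/s * 3600 s * 1.60218e-13 J/MeV, per gram, in mGy)
MEV_TO_MGY_G_PER_MBQ_H <- 1.60218e-13 * 3.6e9 * 1e6

# mass energy-absorption coefficient of water at 511 keV, cm^2/g
MU_EN_511_CM2_G <- 0.0330

#' Self-dose coefficient of a unit-density sphere
#'
#' Mean absorbed dose per unit time-integrated activity for activity
#' distributed uniformly in a unit-density sphere of mass `m` grams:
#' `d = (Delta_beta * phi_beta + Delta_gamma * phi_gamma(m)) / m`, where
#' `Delta_beta` is the mean beta energy emitted per decay and
#' `Delta_gamma` the annihilation-photon energy per decay
#' (2 x 0.511 MeV x positron yield). The beta absorbed fraction is taken
#' as 1 (positron range is small against the sphere sizes of interest);
#' the photon absorbed fraction uses a mean-chord exponential-absorption
#' approximation `phi = 1 - exp(-mu_en * 3 r / 4)` with the 511-keV mass
#' energy-absorption coefficient of water — an approximate model, adequate
#' for the gram-to-hectogram masses used for salivary glands.
#'
#' @param mass_g Sphere mass in grams (> 0), vectorised.
#' @param nuclide A [nuclide] object.
#' @param photon_model `"attenuation"` (default) or `"none"` (beta only).
#' @return Dose coefficient in mGy/(MBq·h).
#' @export
sphere_dose_coefficient <- function(mass_g, nuclide = nuclide_f18(),
                                    photon_model = c("attenuation", "none")) {
  nuclide <- as_nuclide(nuclide)
  photon_model <- match.arg(photon_model)
  if (any(mass_g <= 0)) stop("mass_g must be positive")
  delta_beta <- nuclide$mean_beta_energy_mev * nuclide$positron_yield
  delta_gamma <- nuclide$photon_energy_mev * nuclide$photons_per_decay
  radius_cm <- (3 * mass_g / (4 * pi))^(1 / 3)  # unit density
  phi_gamma <- switch(photon_model,
    attenuation = 1 - exp(-MU_EN_511_CM2_G * 0.75 * radius_cm),
    none = 0)
  MEV_TO_MGY_G_PER_MBQ_H * (delta_beta + delta_gamma * phi_gamma) / mass_g
}

#' Power-law fit of sphere dose coefficients against mass
#'
#' Ordinary least squares of `log d` on `log m`, returning `d = a m^b`.
#' Exact (zero residual) for any input lying on a power law, in particular
#' for any two points.
#'
#' @param masses_g Sphere masses (g), >= 2 strictly positive values.
#' @param coefficients Dose coefficients at those masses, strictly positive.
#' @return Object of class `sphere_fit`: list with `a`, `b`, `masses_g`,
#'   `coefficients` and `residual_norm` (RMS log residual).
#' @export
fit_power_law <- function(masses_g, coefficients) {
  if (length(masses_g) < 2L || length(coefficients) != length(masses_g))
    stop("need at least 2 (mass, coefficient) pairs of equal length")
  if (any(masses_g <= 0) || any(coefficients <= 0))
    stop("masses and coefficients must be strictly positive")
  fit <- stats::lm(log(coefficients) ~ log(masses_g))
  structure(list(a = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 masses_g = masses_g, coefficients = coefficients,
                 residual_norm = sqrt(mean(stats::residuals(fit)^2))),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> d = %.4g * m^%.4g  (RMS log residual %.2g, %d points)\n",
              x$a, x$b, x$residual_norm, length(x$masses_g)))
  invisible(x)
}

#' Sphere-model organ dose
#'
#' Absorbed dose of an organ treated as a uniform unit-density sphere:
#' the power-law dose coefficient at the organ mass times the organ's
#' residence time, `D = a m^b * tau`.
#'
#' @param tau Residence time (h), >= 0.
#' @param mass_g Organ mass (g), > 0.
#' @param fit A [fit_power_law()] result.
#' @return Absorbed dose in mGy/MBq.
#' @export
salivary_gland_dose <- function(tau, mass_g, fit) {
  if (tau < 0) stop("tau must be non-negative")
  if (mass_g <= 0) stop("mass_g must be positive")
  fit$a * mass_g^fit$b * tau
}
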