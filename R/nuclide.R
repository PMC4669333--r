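#' Radionuclide physical data
#'
#' Container for the decay data a dosimetry calculation needs: physical
#' half-life, positron yield, mean beta-plus energy per decay and the
#' annihilation-photon line. The decay constant is derived as
#' `log(2) / half_life` and all internal bookkeeping is in hours.
#'
#' @param name Nuclide label, e.g. `"F-18"`.
#' @param half_life_h Physical half-life in hours (> 0).
#' @param positron_yield Positrons per decay, in (0, 1].
#' @param mean_beta_energy_mev Mean beta-plus energy per decay (MeV).
#' @param photon_energy_mev Photon energy (MeV); 0.511 for annihilation.
#'
#' @return An object of class `nuclide`: a list with the fields above plus
#'   `photons_per_decay` (two annihilation photons per positron) and
#'   `decay_constant_h` (h^-1).
#' @examples
#' f18 <- nuclide_f18()
#' f18$decay_constant_h * f18$half_life_h  # log(2)
#' @export
nuclide <- function(name, half_life_h, positron_yield,
                    mean_beta_energy_mev, photon_energy_mev = 0.511) {
  stopifnot(is.numeric(half_life_h), length(half_life_h) == 1L)
  if (!is.finite(half_life_h) || half_life_h <= 0)
    stop("half_life_h must be a positive finite number")
  if (positron_yield <= 0 || positron_yield > 1)
    stop("positron_yield must be in (0, 1]")
  structure(list(
    name = name,
    half_life_h = half_life_h,
    positron_yield = positron_yield,
    mean_beta_energy_mev = mean_beta_energy_mev,
    photon_energy_mev = photon_energy_mev,
    photons_per_decay = 2 * positron_yield,
    decay_constant_h = log(2) / half_life_h
  ), class = "nuclide")
}

#' Fluorine-18 decay data
#'
#' Half-life 109.77 min, positron yield 0.967, mean beta-plus energy
#' 0.2498 MeV per decay (ICRP Publication 107 decay data).
#'
#' @return A [nuclide] object for F-18.
#' @export
nuclide_f18 <- function() {
  nuclide("F-18", half_life_h = 109.77 / 60, positron_yield = 0.967,
          mean_beta_energy_mev = 0.2498)
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %.4g h, positron yield %.3f, lambda = %.5g /h\n",
              x$name, x$half_life_h, x$positron_yield, x$decay_constant_h))
  invisible(x)
}

#' Maximum theoretical residence time
#'
#' The time integral of a non-clearing whole-body activity fraction of 1,
#' `T1/2 / log(2)` hours. The sum of all source-organ residence times plus
#' the remainder equals this value by construction.
#'
#' @param nuclide A [nuclide] object.
#' @return Hours (2.639 h for F-18).
#' @export
max_residence_time <- function(nuclide = nuclide_f18()) {
  nuclide$half_life_h / log(2)
}

as_nuclide <- function(x) {
  if (inherits(x, "nuclide")) return(x)
  stop("expected a 'nuclide' object; see nuclide() / nuclide_f18()")
}
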