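#' Bundled reference residence times
#'
#' Mean residence times (h) of the measured source organs and the
#' remainder from a published whole-body PET dosimetry study of an F-18
#' NIS tracer in non-human primates (two animals, mean and SD). These are
#' inputs for consistency checks and for running the dose stage without
#' the kinetics stage.
#'
#' @return data.frame with `organ`, `tau_h`, `sd_h`.
#' @export
reference_residence_times <- function() {
  utils::read.csv(system.file("extdata", "reference_residence_times.csv",
                              package = "petdosim", mustWork = TRUE),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Bundled reference organ doses
#'
#' Organ absorbed doses (mGy/MBq) for a 70-kg adult from the same
#' reference study; `sphere_model == 1` flags salivary glands dosed with
#' the unit-density-sphere model.
#'
#' @return data.frame with `organ`, `dose_mgy_per_mbq`, `sd`,
#'   `sphere_model`.
#' @export
reference_organ_doses <- function() {
  utils::read.csv(system.file("extdata", "reference_organ_doses.csv",
                              package = "petdosim", mustWork = TRUE),
                  comment.char = "#", stringsAsFactors = FALSE)
}
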