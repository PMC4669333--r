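#' Organ kinetic model
#'
#' Parametric decay-corrected time-activity model for one organ, expressed
#' as a fraction of injected activity. Four shapes cover the kinetic
#' patterns seen with a NIS-avid tracer:
#' \describe{
#'   \item{`biexp_washout`}{`A1 exp(-l1 t) + A2 exp(-l2 t)` — vascular
#'     organs with an early peak and washout; a rate of 0 gives a retained
#'     (constant) component.}
#'   \item{`uptake_to_plateau`}{`F (1 - exp(-l t))` — accumulating organs
#'     such as the stomach wall and salivary glands.}
#'   \item{`constant_fraction`}{`F` — stable trapping (thyroid).}
#'   \item{`cumulative_bladder`}{`F (1 - exp(-l t))` — urine accumulating
#'     in the bladder, flagged so downstream dosimetry applies the dynamic
#'     voiding model instead of the plain trapezoid estimate.}
#' }
#' Amplitudes are dimensionless fractions of injected activity; rates are
#' biologic rate constants in 1/h (physical decay is applied separately).
#'
#' @param organ Organ name.
#' @param kind One of the four model kinds above.
#' @param A1,lambda1,A2,lambda2 Bi-exponential amplitudes and rates.
#' @param F,lambda Plateau fraction and uptake rate, or constant fraction.
#' @param beds Bed position(s) the organ's VOI spans in the default
#'   whole-body geometry (head = bed 1, thorax = 2, abdomen = 3, pelvis = 4).
#' @return An object of class `organ_model`.
#' @export
organ_model <- function(organ,
                        kind = c("biexp_washout", "uptake_to_plateau",
                                 "constant_fraction", "cumulative_bladder"),
                        A1 = 0, lambda1 = 0, A2 = 0, lambda2 = 0,
                        F = 0, lambda = 0, beds = 1L) {
  kind <- match.arg(kind)
  pars <- switch(kind,
    biexp_washout = c(A1 = A1, lambda1 = lambda1, A2 = A2, lambda2 = lambda2),
    uptake_to_plateau = c(F = F, lambda = lambda),
    constant_fraction = c(F = F),
    cumulative_bladder = c(F = F, lambda = lambda))
  amps <- pars[grep("^(A|F)", names(pars))]
  rates <- pars[grep("^lambda", names(pars))]
  if (any(amps < 0)) stop("amplitudes must be non-negative")
  if (length(rates) && any(rates < 0)) stop("rate constants must be non-negative")
  structure(list(organ = organ, kind = kind, parameters = pars,
                 beds = as.integer(beds)), class = "organ_model")
}

#' Evaluate an organ model (decay-corrected fraction of injected activity)
#'
#' @param model An [organ_model()].
#' @param time_h Times post-injection, hours.
#' @return Fraction of injected activity (decay-corrected) at each time.
#' @export
fraction_at <- function(model, time_h) {
  p <- model$parameters
  switch(model$kind,
    biexp_washout = p[["A1"]] * exp(-p[["lambda1"]] * time_h) +
      p[["A2"]] * exp(-p[["lambda2"]] * time_h),
    uptake_to_plateau = ,
    cumulative_bladder = p[["F"]] * (1 - exp(-p[["lambda"]] * time_h)),
    constant_fraction = rep(p[["F"]], length(time_h)))
}

#' Closed-form residence time of an organ model
#'
#' The time integral from 0 to infinity of the decay-corrected fraction
#' multiplied by physical decay `exp(-lambda_p t)`:
#' a constant fraction `F` integrates to `F / lambda_p`, a mono-exponential
#' washout `A exp(-l t)` to `A / (l + lambda_p)` and an uptake curve
#' `F (1 - exp(-l t))` to `F l / (lambda_p (l + lambda_p))`. Serves as the
#' analytic ground truth for the trapezoid-based estimator.
#'
#' @param model An [organ_model()].
#' @param nuclide A [nuclide] object.
#' @return Residence time in hours.
#' @export
analytic_residence <- function(model, nuclide = nuclide_f18()) {
  lp <- as_nuclide(nuclide)$decay_constant_h
  p <- model$parameters
  switch(model$kind,
    biexp_washout = p[["A1"]] / (p[["lambda1"]] + lp) +
      p[["A2"]] / (p[["lambda2"]] + lp),
    uptake_to_plateau = ,
    cumulative_bladder = p[["F"]] * p[["lambda"]] /
      (lp * (p[["lambda"]] + lp)),
    constant_fraction = p[["F"]] / lp)
}

hl_rate <- function(half_time_min) log(2) / (half_time_min / 60)

#' Default organ kinetic models
#'
#' Twelve source organs with shapes qualitatively emulating a NIS tracer in
#' a primate: early vascular peaks with washout in heart contents, lungs,
#' brain and kidneys; accumulation to a plateau in stomach, salivary
#' glands, olfactory mucosa and esophagus; a stable thyroid fraction; and
#' cumulative urinary-bladder filling. The parameters are plausible-shape
#' defaults, not fits to any measured dataset.
#'
#' @return Named list of [organ_model()] objects.
#' @export
default_organ_models <- function() {
  m <- list(
    organ_model("lungs", "biexp_washout", A1 = 0.090, lambda1 = hl_rate(8),
                A2 = 0.025, lambda2 = hl_rate(15), beds = 2L),
    organ_model("heart_contents", "biexp_washout", A1 = 0.045,
                lambda1 = hl_rate(8), A2 = 0.012, lambda2 = hl_rate(15),
                beds = 2L),
    # small retained component: residual blood pool / choroid plexus uptake
    organ_model("brain", "biexp_washout", A1 = 0.0075, lambda1 = hl_rate(10),
                A2 = 0.0025, lambda2 = 0, beds = 1L),
    organ_model("kidneys", "biexp_washout", A1 = 0.035, lambda1 = hl_rate(6),
                A2 = 0.012, lambda2 = hl_rate(15), beds = 3L),
    organ_model("stomach", "uptake_to_plateau", F = 0.20,
                lambda = hl_rate(20), beds = 3L),
    organ_model("urinary_bladder", "cumulative_bladder", F = 0.25,
                lambda = hl_rate(30), beds = 4L),
    organ_model("thyroid", "constant_fraction", F = 0.005, beds = 1L),
    organ_model("olfactory_mucosa", "uptake_to_plateau", F = 0.004,
                lambda = hl_rate(15), beds = 1L),
    organ_model("esophagus", "uptake_to_plateau", F = 0.003,
                lambda = hl_rate(30), beds = 2:3),
    organ_model("parotid_gland", "uptake_to_plateau", F = 0.006,
                lambda = hl_rate(20), beds = 1L),
    organ_model("sublingual_gland", "uptake_to_plateau", F = 0.0015,
                lambda = hl_rate(20), beds = 1L),
    organ_model("submandibular_gland", "uptake_to_plateau", F = 0.003,
                lambda = hl_rate(20), beds = 1L)
  )
  stats::setNames(m, vapply(m, `[[`, "", "organ"))
}

#' Default whole-blood kinetic model
#'
#' Declining bi-exponential whole-blood fraction (peak immediately after
#' the bolus, fast 10-min and slower 15-min biologic components).
#'
#' @return An [organ_model()] for whole blood.
#' @export
default_blood_model <- function() {
  organ_model("blood", "biexp_washout", A1 = 0.28, lambda1 = hl_rate(10),
              A2 = 0.12, lambda2 = hl_rate(15))
}

#' Default venous blood-draw times
#'
#' @return Minutes post-injection: 0 (pre-injection), 0.25, 4, 10, 21, 35,
#'   50, 70, 115 and 130 min.
#' @export
default_blood_times <- function() {
  c(0, 0.25, 4, 10, 21, 35, 50, 70, 115, 130)
}

#' Synthetic-subject specification
#'
#' Bundles body mass, injected activity, organ kinetic models, the blood
#' model and acquisition imperfections (per-frame recovery fraction and
#' multiplicative measurement noise) into one reproducible object.
#'
#' @param body_mass_kg Body mass (kg); default 5.5 (an adult cynomolgus
#'   macaque).
#' @param injected_mbq_per_kg Injected activity per body mass (MBq/kg).
#' @param organ_models Named list of [organ_model()] objects.
#' @param blood_model Whole-blood [organ_model()].
#' @param blood_mass_fraction Blood mass as a fraction of body mass.
#' @param recovery Per-frame whole-body recovery fraction in (0, 1];
#'   recycled to the number of frames at sampling time.
#' @param noise_sd Relative SD of multiplicative log-normal noise applied
#'   to every VOI total (0 disables noise).
#' @param nuclide A [nuclide] object.
#' @return An object of class `phantom_spec`.
#' @export
make_phantom <- function(body_mass_kg = 5.5, injected_mbq_per_kg = 24.93,
                         organ_models = default_organ_models(),
                         blood_model = default_blood_model(),
                         blood_mass_fraction = 0.054, recovery = 1,
                         noise_sd = 0, nuclide = nuclide_f18()) {
  if (length(organ_models) == 0L) stop("organ model list must not be empty")
  if (body_mass_kg <= 0) stop("body_mass_kg must be positive")
  if (any(recovery <= 0) || any(recovery > 1))
    stop("recovery fractions must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(organ_models)))
    names(organ_models) <- vapply(organ_models, `[[`, "", "organ")
  # total instantaneous fraction (organs + blood) must never exceed 1
  grid <- c(0, 10^seq(-3, log10(6), length.out = 200))
  tot <- rowSums(vapply(c(organ_models, list(blood = blood_model)),
                        fraction_at, numeric(length(grid)), time_h = grid))
  if (tot[1] > 1)
    stop("organ + blood fractions exceed 1 at t = 0")
  if (max(tot) > 1)
    stop(sprintf("organ + blood fractions exceed 1 (max %.3f)", max(tot)))
  structure(list(
    body_mass_kg = body_mass_kg,
    injected_mbq_per_kg = injected_mbq_per_kg,
    injected_mbq = body_mass_kg * injected_mbq_per_kg,
    organ_models = organ_models,
    blood_model = blood_model,
    blood_mass_fraction = blood_mass_fraction,
    recovery = recovery,
    noise_sd = noise_sd,
    nuclide = nuclide
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %.3g kg, %.4g MBq injected, %d organ models, noise SD %.3g\n",
              x$body_mass_kg, x$injected_mbq, length(x$organ_models), x$noise_sd))
  invisible(x)
}

# mean-one multiplicative log-normal noise with relative SD `sd`
noise_factor <- function(n, sd) {
  if (sd == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + sd^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Sample a synthetic biodistribution on an acquisition schedule
#'
#' Evaluates every organ model at the organ's bed midtime within each
#' frame, then emits the activity a scanner reconstruction would report:
#' decay-corrected to injection time, scaled by the frame's whole-body
#' recovery fraction, with multiplicative log-normal noise. The whole-body
#' VOI carries the full injected activity (no excretion out of the field
#' of view) times recovery and noise. Closed-form ground-truth residence
#' times are attached for parameter-recovery testing.
#'
#' @param phantom A [make_phantom()] specification.
#' @param schedule A [scan_schedule]; defaults to [default_schedule()].
#' @param seed Integer seed; the dataset is bit-reproducible given
#'   (phantom, schedule, seed).
#' @return An object of class `synthetic_dataset`: list with `organ_table`
#'   (frame, organ, midtime_min, activity_mbq — decay-corrected),
#'   `wholebody` (frame, activity_mbq), `injected_mbq`, `truth` (named
#'   vector of analytic residence times, including `blood`), `organ_beds`,
#'   `phantom` and `schedule`.
#' @export
sample_biodistribution <- function(phantom, schedule = default_schedule(),
                                   seed = 1L) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(schedule, "scan_schedule"))
  nf <- length(schedule$frame_starts_min)
  recovery <- rep_len(phantom$recovery, nf)
  a0 <- phantom$injected_mbq
  organs <- names(phantom$organ_models)
  set.seed(as.integer(seed))
  rows <- lapply(organs, function(org) {
    mod <- phantom$organ_models[[org]]
    t_h <- vapply(seq_len(nf), function(f)
      organ_midtime(schedule, f, mod$beds), numeric(1))
    fdc <- fraction_at(mod, t_h)
    data.frame(frame = seq_len(nf), organ = org, midtime_min = t_h * 60,
               activity_mbq = fdc * a0 * recovery *
                 noise_factor(nf, phantom$noise_sd))
  })
  organ_table <- do.call(rbind, rows)
  wholebody <- data.frame(
    frame = seq_len(nf),
    activity_mbq = a0 * recovery * noise_factor(nf, phantom$noise_sd))
  truth <- vapply(phantom$organ_models, analytic_residence, numeric(1),
                  nuclide = phantom$nuclide)
  truth <- c(truth, blood = analytic_residence(phantom$blood_model,
                                               phantom$nuclide))
  structure(list(organ_table = organ_table, wholebody = wholebody,
                 injected_mbq = a0, truth = truth,
                 organ_beds = lapply(phantom$organ_models, `[[`, "beds"),
                 phantom = phantom, schedule = schedule,
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' Sample a synthetic blood curve
#'
#' Physical (not decay-corrected) fraction of injected activity per gram of
#' blood at the requested draw times, as a well counter normalised to the
#' injected activity would report. The draw at t = 0 is a pre-injection
#' blank and is exactly 0.
#'
#' @param phantom A [make_phantom()] specification.
#' @param draw_times_min Draw times, minutes post-injection.
#' @param seed Integer seed for the measurement noise.
#' @return data.frame with `time_min`, `time_h`, `fraction_id_per_g`.
#' @export
sample_blood <- function(phantom, draw_times_min = default_blood_times(),
                         seed = 1L) {
  stopifnot(inherits(phantom, "phantom_spec"))
  if (any(draw_times_min < 0)) stop("draw times must be non-negative")
  t_h <- draw_times_min / 60
  lp <- phantom$nuclide$decay_constant_h
  blood_g <- phantom$blood_mass_fraction * phantom$body_mass_kg * 1000
  frac <- fraction_at(phantom$blood_model, t_h) * exp(-lp * t_h) / blood_g
  frac[draw_times_min == 0] <- 0
  set.seed(as.integer(seed) + 1L)
  frac <- frac * noise_factor(length(frac), phantom$noise_sd)
  data.frame(time_min = draw_times_min, time_h = t_h,
             fraction_id_per_g = frac)
}
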