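#' Recovery correction of a VOI activity
#'
#' Per-frame scanner-calibration correction: the recovery of a frame is the
#' ratio of the decay-corrected whole-body VOI activity to the injected
#' activity, and every organ VOI total in that frame is divided by it. With
#' no activity leaving the field of view the whole-body VOI should account
#' for the full (decay-corrected) injected activity, so recovery < 1
#' reflects reconstruction/calibration losses.
#'
#' @param organ_activity Organ VOI activity (decay-corrected); vectorised.
#' @param wholebody_activity Whole-body VOI activity for the same frame
#'   (decay-corrected), > 0.
#' @param injected_activity Administered activity, > 0, same units.
#' @return Corrected organ activity (`organ_activity / recovery`).
#' @export
recovery_correct <- function(organ_activity, wholebody_activity,
                             injected_activity) {
  if (any(wholebody_activity <= 0)) stop("wholebody_activity must be > 0")
  if (any(injected_activity <= 0)) stop("injected_activity must be > 0")
  recovery <- wholebody_activity / injected_activity
  if (any(recovery > 1.05))
    warning(sprintf("recovery %.3f exceeds 1.05: calibration drift?",
                    max(recovery)))
  organ_activity / recovery
}

#' Build percent-of-injected-dose time-activity curves
#'
#' Places each VOI measurement at its organ's bed midtime (or at the
#' midpoint between the midtimes of spanned beds), reverses the
#' reconstruction's decay correction and divides by the administered
#' activity. Values are stored as dimensionless fractions of injected
#' activity; the physical fraction (`fraction_id`) is what residence-time
#' integration consumes, while the decay-corrected fraction
#' (`fraction_id_dc`) is what the bladder increase-to-maximum fit consumes.
#'
#' @param measurements data.frame with columns `organ`, `frame`,
#'   `activity` (decay-corrected VOI totals; same unit as
#'   `injected_activity`).
#' @param schedule A [scan_schedule].
#' @param injected_activity Administered activity.
#' @param nuclide A [nuclide] object.
#' @param organ_beds Named list mapping organ name to the bed indices its
#'   VOI spans; organs not listed default to bed 1.
#' @return data.frame of class `organ_tacs` with columns `organ`, `time_h`,
#'   `fraction_id`, `fraction_id_dc`, ordered by organ then time.
#' @export
to_tac <- function(measurements, schedule, injected_activity,
                   nuclide = nuclide_f18(), organ_beds = list()) {
  stopifnot(is.data.frame(measurements),
            all(c("organ", "frame", "activity") %in% names(measurements)))
  nuclide <- as_nuclide(nuclide)
  if (injected_activity <= 0) stop("injected_activity must be > 0")
  if (any(measurements$activity < 0)) stop("activities must be non-negative")
  time_h <- mapply(function(org, frm) {
    beds <- organ_beds[[org]]
    if (is.null(beds)) beds <- 1L
    organ_midtime(schedule, frm, beds)
  }, measurements$organ, measurements$frame)
  fraction_id_dc <- measurements$activity / injected_activity
  out <- data.frame(
    organ = measurements$organ,
    time_h = time_h,
    fraction_id = undecay_to_midtime(fraction_id_dc, time_h, nuclide),
    fraction_id_dc = fraction_id_dc)
  out <- out[order(out$organ, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("organ_tacs", "data.frame")
  out
}

#' Extract one organ's TAC
#'
#' @param tacs An `organ_tacs` data.frame from [to_tac()].
#' @param organ Organ name.
#' @return data.frame with that organ's points ordered by time.
#' @export
organ_tac <- function(tacs, organ) {
  out <- tacs[tacs$organ == organ, , drop = FALSE]
  if (nrow(out) == 0L) stop(sprintf("no TAC for organ '%s'", organ))
  rownames(out) <- NULL
  out
}

#' TACs from a synthetic dataset
#'
#' Convenience wrapper: recovery-corrects every frame of a
#' [sample_biodistribution()] dataset and converts to fraction-of-injected
#' -dose TACs.
#'
#' @param dataset A `synthetic_dataset`.
#' @param recovery_mode `"injected"` normalises the whole-body VOI to the
#'   injected activity (default); `"first_frame"` normalises to the first
#'   frame's whole-body VOI instead.
#' @return An `organ_tacs` data.frame (see [to_tac()]).
#' @export
tacs_from_dataset <- function(dataset,
                              recovery_mode = c("injected", "first_frame")) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  recovery_mode <- match.arg(recovery_mode)
  wb <- dataset$wholebody
  ref <- switch(recovery_mode,
                injected = dataset$injected_mbq,
                first_frame = wb$activity_mbq[wb$frame == 1L])
  m <- dataset$organ_table
  corr <- function(x) recovery_correct(
    x, wb$activity_mbq[match(m$frame, wb$frame)], ref)
  # simulated measurement noise legitimately pushes recovery above 1;
  # the calibration-drift warning is only meaningful for real data
  m$activity <- if (dataset$phantom$noise_sd > 0) suppressWarnings(corr(m$activity_mbq))
                else corr(m$activity_mbq)
  to_tac(m[, c("organ", "frame", "activity")], dataset$schedule,
         dataset$injected_mbq, dataset$phantom$nuclide,
         organ_beds = dataset$organ_beds)
}

#' Total activity of a labelled VOI in a voxel volume
#'
#' @param volume 3-D numeric array of activity concentration per voxel
#'   (activity per mL).
#' @param labels Integer array of the same dimension assigning each voxel
#'   to a VOI label (0 = background).
#' @param label VOI label to total.
#' @param voxel_volume_ml Volume of one voxel in mL.
#' @return Total activity: sum of the labelled voxels times voxel volume.
#' @export
voi_total <- function(volume, labels, label, voxel_volume_ml) {
  if (!identical(dim(volume), dim(labels)))
    stop("volume and label map dimensions differ")
  sel <- labels == label
  if (!any(sel)) stop(sprintf("label %s not present in the label map", label))
  sum(volume[sel]) * voxel_volume_ml
}

#' Voxelised ellipsoid phantom (synthetic)
#'
#' Builds a small voxel volume containing uniform-activity ellipsoids, with
#' a matching VOI label map — a synthetic stand-in for a reconstructed PET
#' volume, used to exercise [voi_total()].
#'
#' @param organs data.frame with columns `label`, `cx`, `cy`, `cz`
#'   (centre, mm), `rx`, `ry`, `rz` (semi-axes, mm) and `activity`
#'   (total activity in the organ).
#' @param dim_xyz Integer grid dimensions.
#' @param voxel_mm Isotropic voxel size (mm).
#' @return List with `volume` (activity per mL), `labels`,
#'   `voxel_volume_ml` and `organ_totals` (bookkeeping truth).
#' @export
make_voxel_phantom <- function(organs, dim_xyz = c(48L, 48L, 48L),
                               voxel_mm = 2.6) {
  vol <- array(0, dim_xyz)
  lab <- array(0L, dim_xyz)
  vx_ml <- voxel_mm^3 / 1000
  cx <- (seq_len(dim_xyz[1]) - 0.5) * voxel_mm
  cy <- (seq_len(dim_xyz[2]) - 0.5) * voxel_mm
  cz <- (seq_len(dim_xyz[3]) - 0.5) * voxel_mm
  totals <- numeric(nrow(organs))
  for (i in seq_len(nrow(organs))) {
    o <- organs[i, ]
    d2 <- outer(outer(((cx - o$cx) / o$rx)^2, ((cy - o$cy) / o$ry)^2, "+"),
                ((cz - o$cz) / o$rz)^2, "+")
    inside <- d2 <= 1
    n <- sum(inside)
    if (n == 0L) stop(sprintf("organ row %d covers no voxel", i))
    vol[inside] <- o$activity / (n * vx_ml)
    lab[inside] <- o$label
    totals[i] <- o$activity
  }
  list(volume = vol, labels = lab, voxel_volume_ml = vx_ml,
       organ_totals = stats::setNames(totals, organs$label))
}
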