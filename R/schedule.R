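#' Dynamic whole-body acquisition schedule
#'
#' A multi-frame, multi-bed PET acquisition: each whole-body frame is a
#' sweep over `beds_per_frame` axial bed positions, acquired back to back
#' with a fixed repositioning gap between beds. Frame start times are
#' authoritative; the (approximate) gap between frames is kept as metadata
#' only. Per-bed durations typically increase over frames to compensate for
#' physical decay.
#'
#' @param frame_starts_min Start time of each frame, minutes post-injection,
#'   strictly increasing.
#' @param bed_durations_s Acquisition time per bed position for each frame,
#'   seconds; one value per frame, all positive.
#' @param beds_per_frame Number of bed positions per frame.
#' @param inter_bed_gap_s Repositioning time between successive beds (s).
#' @param inter_frame_gap_s Approximate gap between frames (s), metadata.
#'
#' @return An object of class `scan_schedule`.
#' @seealso [default_schedule()] for the bundled 8-frame, 5-bed protocol.
#' @export
scan_schedule <- function(frame_starts_min, bed_durations_s,
                          beds_per_frame = 5L, inter_bed_gap_s = 12,
                          inter_frame_gap_s = 30) {
  n <- length(frame_starts_min)
  if (n < 1L) stop("at least one frame is required")
  if (length(bed_durations_s) != n)
    stop("bed_durations_s must have one entry per frame")
  if (any(!is.finite(frame_starts_min)) || any(!is.finite(bed_durations_s)))
    stop("frame starts and bed durations must be finite")
  if (any(bed_durations_s <= 0)) stop("all bed durations must be positive")
  if (beds_per_frame < 1L) stop("beds_per_frame must be >= 1")
  if (inter_bed_gap_s < 0) stop("inter_bed_gap_s must be >= 0")
  if (n > 1L && any(diff(frame_starts_min) <= 0))
    stop("frame start times must be strictly increasing")
  if (n > 1L && any(diff(bed_durations_s) < 0))
    warning("per-bed durations decrease between frames; unusual for a decaying tracer")
  frame_span_min <- (beds_per_frame * bed_durations_s +
                       (beds_per_frame - 1L) * inter_bed_gap_s) / 60
  frame_end_min <- frame_starts_min + frame_span_min
  # a frame must finish (within 1 s) before the next one starts
  if (n > 1L && any(frame_end_min[-n] > frame_starts_min[-1L] + 1 / 60))
    stop("frame overlap: a frame ends after the next frame starts")
  structure(list(
    frame_starts_min = as.numeric(frame_starts_min),
    bed_durations_s = as.numeric(bed_durations_s),
    beds_per_frame = as.integer(beds_per_frame),
    inter_bed_gap_s = inter_bed_gap_s,
    inter_frame_gap_s = inter_frame_gap_s,
    frame_end_min = frame_end_min
  ), class = "scan_schedule")
}

#' Default 8-frame whole-body protocol
#'
#' Eight whole-body frames of five bed positions with a 12-s inter-bed gap;
#' frame starts 0, 3.5, 10.5, 22.5, 39.5, 56.5, 78.5 and 106 min with
#' per-bed durations 15, 60, 120, 180, 180, 240, 300 and 300 s, ending
#' emission scanning at 131.8 min.
#'
#' @return A [scan_schedule].
#' @export
default_schedule <- function() {
  scan_schedule(
    frame_starts_min = c(0, 3.5, 10.5, 22.5, 39.5, 56.5, 78.5, 106),
    bed_durations_s = c(15, 60, 120, 180, 180, 240, 300, 300)
  )
}

#' @export
print.scan_schedule <- function(x, ...) {
  cat(sprintf("<scan_schedule> %d frames x %d beds, %g s inter-bed gap\n",
              length(x$frame_starts_min), x$beds_per_frame, x$inter_bed_gap_s))
  print(data.frame(frame = seq_along(x$frame_starts_min),
                   start_min = x$frame_starts_min,
                   bed_s = x$bed_durations_s,
                   end_min = round(x$frame_end_min, 2)), row.names = FALSE)
  invisible(x)
}

#' End of emission scanning
#'
#' @param schedule A [scan_schedule].
#' @return Minutes post-injection at which the last bed of the last frame
#'   finishes (131.8 min for the default protocol).
#' @export
emission_end <- function(schedule) {
  stopifnot(inherits(schedule, "scan_schedule"))
  max(schedule$frame_end_min)
}

#' Bed midtimes
#'
#' The reference time of each (frame, bed) acquisition: bed `k` (1-based)
#' of a frame starting at `T` with per-bed duration `d` starts at
#' `T + (k-1) * (d + gap)` and its midtime is `start + d/2`. Activity
#' measurements are decay-referenced to these midtimes.
#'
#' @param schedule A [scan_schedule].
#' @return A data.frame with columns `frame`, `bed`, `start_min`,
#'   `midtime_min`, `midtime_h`, ordered by frame then bed. Frame and bed
#'   indices are 1-based.
#' @export
bed_midtimes <- function(schedule) {
  stopifnot(inherits(schedule, "scan_schedule"))
  nf <- length(schedule$frame_starts_min)
  nb <- schedule$beds_per_frame
  frame <- rep(seq_len(nf), each = nb)
  bed <- rep(seq_len(nb), times = nf)
  d <- schedule$bed_durations_s[frame]
  start_min <- schedule$frame_starts_min[frame] +
    (bed - 1L) * (d + schedule$inter_bed_gap_s) / 60
  midtime_min <- start_min + d / 120
  data.frame(frame = frame, bed = bed, start_min = start_min,
             midtime_min = midtime_min, midtime_h = midtime_min / 60)
}

#' Midtime of an organ VOI spanning one or more beds
#'
#' Organs contained in a single bed are referenced to that bed's midtime;
#' organs extending through two (or more) beds are referenced to the
#' midpoint of the spanned beds' midtimes.
#'
#' @param schedule A [scan_schedule].
#' @param frame Frame index (1-based).
#' @param beds Integer vector of bed indices the organ spans.
#' @return Midtime in hours post-injection.
#' @export
organ_midtime <- function(schedule, frame, beds) {
  mt <- bed_midtimes(schedule)
  sel <- mt$frame == frame & mt$bed %in% beds
  if (sum(sel) != length(beds))
    stop(sprintf("frame %d / beds %s outside the schedule", frame,
                 paste(beds, collapse = ",")))
  mean(range(mt$midtime_h[sel]))
}

#' Reverse the reconstruction's decay correction
#'
#' Scanner reconstructions report activities decay-corrected to the
#' injection time; the physical activity present at the bed midtime is
#' recovered by re-applying the decay factor,
#' `A_physical = A_corrected * exp(-lambda * t)`.
#'
#' @param activity Decay-corrected activity (any unit), non-negative.
#' @param time_h Reference time (bed midtime, or midpoint between spanned
#'   beds' midtimes) in hours post-injection.
#' @param nuclide A [nuclide] object.
#' @return Physical activity at `time_h`.
#' @export
undecay_to_midtime <- function(activity, time_h, nuclide = nuclide_f18()) {
  nuclide <- as_nuclide(nuclide)
  if (any(activity < 0, na.rm = TRUE)) stop("activity must be non-negative")
  if (any(time_h < 0)) stop("reference time must be non-negative")
  activity * exp(-nuclide$decay_constant_h * time_h)
}

#' Apply a decay correction (inverse of [undecay_to_midtime()])
#'
#' @inheritParams undecay_to_midtime
#' @return Decay-corrected activity referenced to injection time.
#' @export
decay_correct <- function(activity, time_h, nuclide = nuclide_f18()) {
  nuclide <- as_nuclide(nuclide)
  if (any(activity < 0, na.rm = TRUE)) stop("activity must be non-negative")
  activity * exp(nuclide$decay_constant_h * time_h)
}
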