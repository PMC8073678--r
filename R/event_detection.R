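# Smile event detection: boxcar smoothing, supra-threshold run
# segmentation, minimum-duration filtering, and Social/Simple
# classification by AU06 co-activation.

#' Boxcar (moving-average) smoothing
#'
#' Smooths a per-frame intensity signal with a width-`width_frames`
#' boxcar. An even width has no centre frame; the window is anchored as
#' `{t - floor(w/2), ..., t + w - 1 - floor(w/2)}` (for the default width
#' 4: `{t-2, t-1, t, t+1}`). Near the edges the window is intersected
#' with the array bounds and the mean renormalized over the in-bounds
#' frames, so constant signals are fixed points and output values never
#' leave the range of the input.
#'
#' @param signal Numeric vector.
#' @param width_frames Integer window width in frames, >= 1; default 4.
#' @return Numeric vector of the same length.
#' @export
smooth_boxcar <- function(signal, width_frames = 4L) {
  if (!is.numeric(width_frames) || length(width_frames) != 1L ||
      width_frames < 1) {
    stop("`width_frames` must be a single integer >= 1", call. = FALSE)
  }
  w <- as.integer(width_frames)
  n <- length(signal)
  if (n == 0L) stop("`signal` must have length >= 1", call. = FALSE)
  left <- w %/% 2L
  right <- w - 1L - left
  t <- seq_len(n)
  lo <- pmax(1L, t - left)
  hi <- pmin(n, t + right)
  cs <- c(0, cumsum(signal))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect supra-threshold activation intervals
#'
#' Returns the maximal runs of frames on which the (smoothed) AU signal
#' is at or above the activation threshold `tau` and the frame passes the
#' validity mask. Intervals are inclusive frame-index ranges (1-based),
#' ordered, non-overlapping, and separated by at least one inactive frame.
#'
#' @param signal Numeric vector of smoothed intensities.
#' @param valid_mask Logical vector of the same length; `NULL` means all
#'   frames valid.
#' @param tau Activation threshold on the 0--5 intensity scale; default
#'   0.5. Activation is inclusive (`signal >= tau`).
#' @return A data.frame with columns `start_idx`, `end_idx` (possibly
#'   zero rows).
#' @export
detect_active_intervals <- function(signal, valid_mask = NULL, tau = 0.5) {
  n <- length(signal)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  if (length(valid_mask) != n) {
    stop("`signal` and `valid_mask` must have the same length", call. = FALSE)
  }
  active <- (signal >= tau) & valid_mask
  if (!any(active)) {
    return(data.frame(start_idx = integer(), end_idx = integer()))
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values
  data.frame(start_idx = starts[on], end_idx = ends[on])
}

#' Drop activation intervals shorter than a minimum duration
#'
#' Facial expressions briefer than `min_s` seconds are excluded as
#' tracker noise rather than genuine expressive events; an interval of
#' `k` frames at `fps` frames/s lasts `k / fps` seconds and is kept when
#' that is at least `min_s` (the exclusion rule is strictly-shorter-than).
#'
#' @param intervals Data.frame from [detect_active_intervals()].
#' @param fps Frames per second, > 0.
#' @param min_s Minimum event duration in seconds; default 1.0.
#' @return The filtered data.frame, order preserved.
#' @export
filter_min_duration <- function(intervals, fps, min_s = 1.0) {
  stopifnot(is.numeric(fps), fps > 0)
  if (!is.numeric(min_s) || min_s < 0) {
    stop("`min_s` must be non-negative", call. = FALSE)
  }
  if (nrow(intervals) == 0L) return(intervals)
  dur <- (intervals$end_idx - intervals$start_idx + 1L) / fps
  intervals[dur >= min_s, , drop = FALSE]
}

#' Classify AU12 activation episodes as Social or Simple Smiles
#'
#' Every duration-filtered AU12 interval becomes exactly one smile event.
#' An event is a Social Smile (`"SO"`) when AU06 is co-active on at least
#' `social_overlap_threshold` of its frames, otherwise a Simple Smile
#' (`"SI"`). AU06 intervals never generate events on their own: the smile
#' taxonomy is anchored on AU12.
#'
#' @param au12_intervals Duration-filtered AU12 intervals
#'   (data.frame with `start_idx`, `end_idx`).
#' @param au06_intervals AU06 activation intervals from the same segment
#'   (not duration-filtered).
#' @param fps Frames per second.
#' @param timestamps Per-frame times for the segment (seconds).
#' @param au12_smooth,au06_smooth Smoothed intensity vectors used for the
#'   event means.
#' @param social_overlap_threshold Fraction in (0, 1\] of event frames on
#'   which AU06 must be active for the `"SO"` label; default 0.5.
#' @param subject_id,segment_id Identifiers copied onto each event.
#' @return A tibble of smile events with columns `subject_id`,
#'   `segment_id`, `smile_type`, `onset_s`, `offset_s`, `duration_s`,
#'   `mean_au12`, `mean_au06`, `au06_overlap_frac`, `start_idx`,
#'   `end_idx`.
#' @export
classify_smiles <- function(au12_intervals, au06_intervals, fps, timestamps,
                            au12_smooth, au06_smooth,
                            social_overlap_threshold = 0.5,
                            subject_id = NA_character_, segment_id = NA_integer_) {
  if (!is.numeric(social_overlap_threshold) ||
      length(social_overlap_threshold) != 1L ||
      social_overlap_threshold <= 0 || social_overlap_threshold > 1) {
    stop("`social_overlap_threshold` must lie in (0, 1]", call. = FALSE)
  }
  n_ev <- nrow(au12_intervals)
  if (n_ev == 0L) return(empty_smile_events())

  covered <- logical(length(timestamps))
  if (nrow(au06_intervals) > 0L) {
    for (k in seq_len(nrow(au06_intervals))) {
      covered[au06_intervals$start_idx[k]:au06_intervals$end_idx[k]] <- TRUE
    }
  }

  onset <- offset <- dur <- m12 <- m06 <- ovl <- numeric(n_ev)
  for (k in seq_len(n_ev)) {
    idx <- au12_intervals$start_idx[k]:au12_intervals$end_idx[k]
    feats <- event_features(idx, au12_smooth, au06_smooth, fps, timestamps)
    onset[k] <- feats$onset_s
    offset[k] <- feats$offset_s
    dur[k] <- feats$duration_s
    m12[k] <- feats$mean_au12
    m06[k] <- feats$mean_au06
    ovl[k] <- mean(covered[idx])
  }
  tibble::new_tibble(list(
    subject_id = rep(subject_id, n_ev),
    segment_id = rep(as.integer(segment_id), n_ev),
    smile_type = ifelse(ovl >= social_overlap_threshold, "SO", "SI"),
    onset_s = onset,
    offset_s = offset,
    duration_s = dur,
    mean_au12 = m12,
    mean_au06 = m06,
    au06_overlap_frac = ovl,
    start_idx = au12_intervals$start_idx,
    end_idx = au12_intervals$end_idx
  ), nrow = n_ev)
}

empty_smile_events <- function() {
  tibble::new_tibble(list(
    subject_id = character(), segment_id = integer(), smile_type = character(),
    onset_s = numeric(), offset_s = numeric(), duration_s = numeric(),
    mean_au12 = numeric(), mean_au06 = numeric(),
    au06_overlap_frac = numeric(), start_idx = integer(), end_idx = integer()
  ), nrow = 0L)
}

#' Per-event features
#'
#' Computes the descriptive features of one event: arithmetic means of
#' the smoothed AU12 and AU06 signals over the event frames, the event
#' duration as frame count over frame rate, and onset/offset times.
#'
#' @param event_idx Integer vector of frame indices forming the event.
#' @param au12_smooth,au06_smooth Smoothed intensity vectors.
#' @param fps Frames per second.
#' @param timestamps Per-frame times (seconds).
#' @return A list with `onset_s`, `offset_s`, `duration_s`, `mean_au12`,
#'   `mean_au06`.
#' @export
event_features <- function(event_idx, au12_smooth, au06_smooth, fps,
                           timestamps) {
  if (length(event_idx) == 0L) {
    stop("event frame range is empty", call. = FALSE)
  }
  list(
    onset_s = timestamps[event_idx[1L]],
    offset_s = timestamps[event_idx[length(event_idx)]],
    duration_s = length(event_idx) / fps,
    mean_au12 = mean(au12_smooth[event_idx]),
    mean_au06 = mean(au06_smooth[event_idx])
  )
}

#' Detect smile events in one segment
#'
#' Runs the full per-segment chain: boxcar smoothing of AU12 and AU06,
#' supra-threshold run detection on both, minimum-duration filtering of
#' the AU12 runs, and Social/Simple classification by AU06 co-activation.
#'
#' @param segment An [au_frame_series()] segment.
#' @param smooth_width_frames Boxcar width in frames; default 4.
#' @param tau Activation threshold on the 0--5 scale; default 0.5.
#' @param min_event_s Minimum event duration in seconds; default 1.0.
#' @param social_overlap_threshold AU06 co-activation fraction for the
#'   Social label; default 0.5.
#' @return A tibble of smile events (see [classify_smiles()]).
#' @export
detect_smile_events <- function(segment, smooth_width_frames = 4L,
                                tau = 0.5, min_event_s = 1.0,
                                social_overlap_threshold = 0.5) {
  stopifnot(inherits(segment, "au_frame_series"))
  s12 <- smooth_boxcar(segment$au12, smooth_width_frames)
  s06 <- smooth_boxcar(segment$au06, smooth_width_frames)
  iv12 <- detect_active_intervals(s12, segment$valid_mask, tau)
  iv06 <- detect_active_intervals(s06, segment$valid_mask, tau)
  iv12 <- filter_min_duration(iv12, segment$fps, min_event_s)
  classify_smiles(iv12, iv06, segment$fps, segment$timestamps, s12, s06,
                  social_overlap_threshold,
                  subject_id = segment$subject_id,
                  segment_id = segment$segment_id)
}

#' Detect smile events across all segments of a recording set
#'
#' @param recording A [recording_set()].
#' @inheritParams detect_smile_events
#' @return A tibble of smile events over all segments (zero rows if the
#'   recording has no segments). Events never span a segment boundary.
#' @export
smile_events <- function(recording, smooth_width_frames = 4L, tau = 0.5,
                         min_event_s = 1.0, social_overlap_threshold = 0.5) {
  stopifnot(inherits(recording, "recording_set"))
  evs <- lapply(recording$segments, detect_smile_events,
                smooth_width_frames = smooth_width_frames, tau = tau,
                min_event_s = min_event_s,
                social_overlap_threshold = social_overlap_threshold)
  if (length(evs) == 0L) return(empty_smile_events())
  do.call(rbind, evs)
}
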