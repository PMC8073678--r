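# Ingestion of OpenFace-dialect AU time series: reading, confidence gating,
# and segmentation at tracking dropouts.

#' Construct an AU frame series
#'
#' An `au_frame_series` holds one continuous stretch of per-frame facial
#' Action Unit estimates for a single subject: timestamps, the tracker's
#' per-frame confidence score C in \[0, 1\], AU12 (lip-corner puller) and
#' AU06 (cheek raiser) intensities on the 0--5 OpenFace scale, and a
#' validity mask derived from the confidence gate.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param timestamps Numeric vector of frame times in seconds, strictly
#'   increasing.
#' @param confidence Numeric vector in \[0, 1\], same length as `timestamps`.
#' @param au12,au06 Numeric intensity vectors on the 0--5 scale.
#' @param valid_mask Logical vector; `TRUE` marks frames passing the
#'   confidence gate. Defaults to all `TRUE` (gate not yet applied).
#' @param segment_id Non-negative integer; 0 for an unsplit recording.
#' @param fps Frames per second. If `NULL`, inferred as
#'   `1 / median(diff(timestamps))`.
#' @param gate_threshold Confidence threshold used to build `valid_mask`,
#'   or `NA` if the gate has not been applied.
#' @param validate Logical; skip invariant checks when `FALSE` (internal
#'   fast path).
#'
#' @return An object of class `au_frame_series`.
#' @seealso [read_openface_csv()], [apply_confidence_gate()],
#'   [split_at_dropouts()]
#' @export
au_frame_series <- function(subject_id, timestamps, confidence, au12, au06,
                            valid_mask = NULL, segment_id = 0L, fps = NULL,
                            gate_threshold = NA_real_, validate = TRUE) {
  n <- length(timestamps)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  if (is.null(fps)) {
    if (n < 2L) {
      stop("cannot infer fps from fewer than 2 frames; supply `fps`",
           call. = FALSE)
    }
    fps <- 1 / stats::median(diff(timestamps))
  }
  x <- structure(
    list(
      subject_id = as.character(subject_id),
      segment_id = as.integer(segment_id),
      timestamps = as.numeric(timestamps),
      fps = as.numeric(fps),
      confidence = as.numeric(confidence),
      au12 = as.numeric(au12),
      au06 = as.numeric(au06),
      valid_mask = as.logical(valid_mask),
      gate_threshold = as.numeric(gate_threshold)
    ),
    class = "au_frame_series"
  )
  if (validate) validate_au_frame_series(x)
  x
}

validate_au_frame_series <- function(x) {
  n <- length(x$timestamps)
  if (n < 1L) stop("au_frame_series must contain at least one frame",
                   call. = FALSE)
  lens <- c(length(x$confidence), length(x$au12), length(x$au06),
            length(x$valid_mask))
  if (any(lens != n)) {
    stop("all per-frame vectors must share the length of `timestamps`",
         call. = FALSE)
  }
  if (n > 1L && any(diff(x$timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(x$fps) || x$fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (any(x$confidence < 0 | x$confidence > 1)) {
    stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  if (any(x$au12 < 0 | x$au12 > 5) || any(x$au06 < 0 | x$au06 > 5)) {
    stop("AU intensities must lie in [0, 5]", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.au_frame_series <- function(x, ...) {
  cat(sprintf(
    "<au_frame_series> subject %s, segment %d: %d frames @ %.2f fps (%.1f s), %d valid\n",
    x$subject_id, x$segment_id, length(x$timestamps), x$fps,
    length(x$timestamps) / x$fps, sum(x$valid_mask)))
  invisible(x)
}

#' @export
length.au_frame_series <- function(x) length(x$timestamps)

#' Convert an AU frame series to a tibble
#'
#' @param x An `au_frame_series`.
#' @param ... Unused.
#' @return A tibble with one row per frame.
#' @method as_tibble au_frame_series
#' @export
as_tibble.au_frame_series <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    segment_id = x$segment_id,
    timestamp = x$timestamps,
    confidence = x$confidence,
    au12 = x$au12,
    au06 = x$au06,
    valid = x$valid_mask
  )
}

# Case/whitespace tolerant header lookup; returns index or NA.
.match_column <- function(header, name) {
  norm <- tolower(trimws(header))
  match(tolower(name), norm)
}

#' Read an OpenFace output CSV
#'
#' Reads one recording in the OpenFace CSV dialect (header row with at
#' least `frame`, `timestamp`, `confidence`, `AU06_r`, `AU12_r`; matching
#' is case- and whitespace-tolerant; other columns are ignored). Rows with
#' non-finite values in any required column are dropped with a message;
#' AU intensities are clipped to the nominal \[0, 5\] scale.
#'
#' @param path Path to the CSV file.
#' @param subject_id Subject identifier to attach; defaults to the file
#'   name without extension.
#' @return An [au_frame_series()] with the frame rate inferred from the
#'   median inter-frame interval. The confidence gate is not yet applied
#'   (all frames marked valid); see [apply_confidence_gate()].
#' @export
read_openface_csv <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  required <- c("frame", "timestamp", "confidence", "AU06_r", "AU12_r")
  idx <- vapply(required, function(nm) .match_column(names(raw), nm), 1L)
  missing <- required[is.na(idx)]
  if (length(missing) > 0L) {
    stop("OpenFace CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ts  <- as.numeric(raw[[idx[["timestamp"]]]])
  cf  <- as.numeric(raw[[idx[["confidence"]]]])
  a06 <- as.numeric(raw[[idx[["AU06_r"]]]])
  a12 <- as.numeric(raw[[idx[["AU12_r"]]]])

  keep <- is.finite(ts) & is.finite(cf) & is.finite(a06) & is.finite(a12)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("%s: dropped %d row(s) with non-finite values",
                    basename(path), n_dropped))
    ts <- ts[keep]; cf <- cf[keep]; a06 <- a06[keep]; a12 <- a12[keep]
  }
  if (length(ts) == 0L) {
    stop("no usable rows in ", path, call. = FALSE)
  }
  if (length(ts) > 1L && any(diff(ts) <= 0)) {
    stop("timestamps are not strictly increasing in ", path, call. = FALSE)
  }
  n_clip <- sum(a12 < 0 | a12 > 5 | a06 < 0 | a06 > 5)
  if (n_clip > 0L) {
    message(sprintf("%s: clipped %d AU intensity value(s) to [0, 5]",
                    basename(path), n_clip))
    a12 <- pmin(pmax(a12, 0), 5)
    a06 <- pmin(pmax(a06, 0), 5)
  }
  cf <- pmin(pmax(cf, 0), 1)
  au_frame_series(subject_id, ts, cf, a12, a06)
}

#' Apply the confidence gate
#'
#' Marks each frame valid when its tracking confidence C strictly exceeds
#' `threshold` (the conventional OpenFace reliability screen is C > 0.75).
#' Frames are masked, not deleted, so gap lengths and total recording time
#' remain computable.
#'
#' @param series An [au_frame_series()].
#' @param threshold Confidence threshold in \[0, 1\]; default 0.75.
#' @return The series with `valid_mask` set and the threshold recorded.
#' @export
apply_confidence_gate <- function(series, threshold = 0.75) {
  stopifnot(inherits(series, "au_frame_series"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop("`threshold` must be a single value in [0, 1]", call. = FALSE)
  }
  series$valid_mask <- series$confidence > threshold
  series$gate_threshold <- threshold
  series
}

#' Construct a recording set
#'
#' A `recording_set` is the result of splitting one gated recording at
#' long tracking dropouts: an ordered list of `au_frame_series` segments
#' plus whole-recording quality accounting (usable seconds, mean
#' confidence, percentage of frames passing the gate).
#'
#' @param subject_id Subject identifier.
#' @param segments List of [au_frame_series()] segments (may be empty).
#' @param usable_seconds Seconds of retained frames summed over segments.
#' @param confidence_mean Mean confidence over all original frames.
#' @param confidence_pct Percentage of original frames passing the gate.
#' @param n_frames_total Number of frames in the original recording.
#' @return An object of class `recording_set`.
#' @export
recording_set <- function(subject_id, segments, usable_seconds,
                          confidence_mean, confidence_pct, n_frames_total) {
  stopifnot(confidence_pct >= 0, confidence_pct <= 100, usable_seconds >= 0)
  structure(
    list(
      subject_id = as.character(subject_id),
      segments = segments,
      usable_seconds = as.numeric(usable_seconds),
      confidence_mean = as.numeric(confidence_mean),
      confidence_pct = as.numeric(confidence_pct),
      n_frames_total = as.integer(n_frames_total)
    ),
    class = "recording_set"
  )
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf(
    "<recording_set> subject %s: %d segment(s), %.2f usable s, mean C %.3f (%.1f%% > gate)\n",
    x$subject_id, length(x$segments), x$usable_seconds,
    x$confidence_mean, x$confidence_pct))
  invisible(x)
}

#' Split a gated recording at tracking dropouts
#'
#' Runs of gate-failing frames longer than `max_gap_s` split the recording
#' into segments and are excluded from usable time. Shorter interior runs
#' are bridged: the frames are retained, their AU intensities linearly
#' interpolated from the flanking valid frames, and they are marked valid
#' so that an expression spanning a brief tracking glitch is not cut in
#' two. Leading and trailing invalid runs have no flanking frame on one
#' side and are always trimmed. Confidence statistics are computed over
#' all original frames.
#'
#' @param series A gated [au_frame_series()] (see [apply_confidence_gate()]).
#' @param max_gap_s Longest dropout, in seconds, bridged inside a segment;
#'   default 0.5 (half the minimum event duration, so bridging alone can
#'   never manufacture a countable event).
#' @return A [recording_set()]. A series with no valid frames yields zero
#'   segments and `usable_seconds = 0`.
#' @export
split_at_dropouts <- function(series, max_gap_s = 0.5) {
  stopifnot(inherits(series, "au_frame_series"))
  if (!is.numeric(max_gap_s) || max_gap_s < 0) {
    stop("`max_gap_s` must be a non-negative number", call. = FALSE)
  }
  n <- length(series$timestamps)
  valid <- series$valid_mask
  conf_mean <- mean(series$confidence)
  conf_pct <- 100 * mean(valid)

  if (!any(valid)) {
    return(recording_set(series$subject_id, list(), 0, conf_mean, conf_pct, n))
  }

  fps <- series$fps
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  # Decide, run by run, whether frames are kept: valid runs always; invalid
  # interior runs only when short enough to bridge.
  keep <- logical(n)
  bridge <- logical(n)
  n_runs <- length(r$lengths)
  for (k in seq_len(n_runs)) {
    if (r$values[k]) {
      keep[starts[k]:ends[k]] <- TRUE
    } else if (k > 1L && k < n_runs && r$lengths[k] / fps <= max_gap_s) {
      keep[starts[k]:ends[k]] <- TRUE
      bridge[starts[k]:ends[k]] <- TRUE
    }
  }

  # Interpolate AU intensities across bridged frames from flanking valid ones.
  if (any(bridge)) {
    vi <- which(valid)
    for (sig in c("au12", "au06")) {
      series[[sig]][bridge] <- stats::approx(
        x = series$timestamps[vi], y = series[[sig]][vi],
        xout = series$timestamps[bridge], method = "linear"
      )$y
    }
  }

  # Maximal kept runs become segments.
  rk <- rle(keep)
  kends <- cumsum(rk$lengths)
  kstarts <- kends - rk$lengths + 1L
  seg_idx <- which(rk$values)
  segments <- vector("list", length(seg_idx))
  usable <- 0
  for (j in seq_along(seg_idx)) {
    i0 <- kstarts[seg_idx[j]]; i1 <- kends[seg_idx[j]]
    idx <- i0:i1
    vm <- valid[idx] | bridge[idx]
    segments[[j]] <- au_frame_series(
      series$subject_id,
      series$timestamps[idx], series$confidence[idx],
      series$au12[idx], series$au06[idx],
      valid_mask = vm, segment_id = j - 1L, fps = fps,
      gate_threshold = series$gate_threshold, validate = FALSE
    )
    usable <- usable + length(idx) / fps
  }
  recording_set(series$subject_id, segments, usable, conf_mean, conf_pct, n)
}

#' Write a normalized per-segment CSV
#'
#' Writes the per-frame content of a recording set (or a single series)
#' as a flat CSV with columns `subject_id`, `segment_id`, `timestamp`,
#' `confidence`, `au12`, `au06`, `valid`, for inspection outside R.
#'
#' @param x A [recording_set()] or [au_frame_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(x, path) {
  if (inherits(x, "au_frame_series")) x <- list(segments = list(x))
  tabs <- lapply(x$segments, as_tibble.au_frame_series)
  out <- do.call(rbind, tabs)
  if (is.null(out)) {
    out <- tibble::tibble(subject_id = character(), segment_id = integer(),
                          timestamp = numeric(), confidence = numeric(),
                          au12 = numeric(), au06 = numeric(),
                          valid = logical())
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
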