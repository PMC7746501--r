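#' Mono audio signal
#'
#' Container for a single-channel amplitude sequence with its sampling rate.
#' All downstream analysis (framing, envelope extraction, detection) operates
#' on this type.
#'
#' @param samples Numeric vector of amplitudes, nominally in [-1, 1].
#' @param rate Sampling rate in Hz; must be positive.
#' @return An object of class `audio_signal` with elements `samples` and
#'   `rate`.
#' @export
audio_signal <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("rate must be a single positive number", call. = FALSE)
  }
  if (length(samples) == 0L) {
    stop("empty audio signal", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("audio samples must all be finite", call. = FALSE)
  }
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, duration(x)))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param signal An [audio_signal].
#' @export
duration <- function(signal) length(signal$samples) / signal$rate

#' Analysis frame grid
#'
#' Defines how a signal is sliced into fixed-length analysis frames. The
#' default is non-overlapping 32 ms frames (512 samples at 16 kHz), the unit
#' of every detection decision and dosimetry metric in this package.
#'
#' @param duration Signal duration in seconds, or an [audio_signal] from
#'   which duration and rate are taken.
#' @param frame_length Frame length in seconds (default 0.032).
#' @param hop Hop between frame starts in seconds; defaults to `frame_length`
#'   (non-overlapping frames). Must satisfy `0 < hop <= frame_length`.
#' @param rate Sampling rate in Hz, ignored when `duration` is an
#'   [audio_signal].
#' @return A `frame_grid` object with fields `frame_length`, `hop`,
#'   `n_frames`, `rate`, `frame_samples`, `hop_samples`.
#' @export
frame_grid <- function(duration, frame_length = 0.032, hop = frame_length,
                       rate = 16000) {
  if (inherits(duration, "audio_signal")) {
    rate <- duration$rate
    n_samples <- length(duration$samples)
  } else {
    n_samples <- floor(duration * rate)
  }
  if (frame_length <= 0) stop("frame_length must be positive", call. = FALSE)
  if (hop <= 0 || hop > frame_length + 1e-12) {
    stop("hop must satisfy 0 < hop <= frame_length", call. = FALSE)
  }
  frame_samples <- round(frame_length * rate)
  hop_samples <- round(hop * rate)
  n_frames <- max(0L, (n_samples - frame_samples) %/% hop_samples + 1L)
  structure(list(frame_length = frame_length, hop = hop,
                 n_frames = as.integer(n_frames), rate = rate,
                 frame_samples = as.integer(frame_samples),
                 hop_samples = as.integer(hop_samples)),
            class = "frame_grid")
}

#' @export
print.frame_grid <- function(x, ...) {
  cat(sprintf("<frame_grid: %d frames of %g ms, hop %g ms @ %g Hz>\n",
              x$n_frames, 1000 * x$frame_length, 1000 * x$hop, x$rate))
  invisible(x)
}

# Centre time (s) of each frame on a grid.
frame_centers <- function(grid) {
  (seq_len(grid$n_frames) - 1L) * grid$hop + grid$frame_length / 2
}

#' Ground-truth speech intervals
#'
#' Ordered, non-overlapping (start, end) spans of speech in seconds over a
#' recording of known total duration. This is the machine-readable stand-in
#' for manual annotation of speech segments.
#'
#' @param intervals Two-column numeric matrix (or data.frame) of start/end
#'   times in seconds; may be empty. Overlapping or adjacent spans are merged.
#' @param total_duration Recording length in seconds; intervals are clipped
#'   to [0, total_duration].
#' @return A `label_track` object with fields `intervals` (n x 2 matrix) and
#'   `total_duration`.
#' @export
label_track <- function(intervals, total_duration) {
  if (is.data.frame(intervals)) intervals <- as.matrix(intervals[, 1:2])
  if (is.null(intervals) || length(intervals) == 0L) {
    intervals <- matrix(numeric(0), ncol = 2)
  }
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  if (total_duration <= 0) stop("total_duration must be > 0", call. = FALSE)
  if (nrow(intervals) > 0) {
    if (any(!is.finite(intervals))) {
      stop("label intervals must be finite", call. = FALSE)
    }
    if (any(intervals[, 2] <= intervals[, 1])) {
      stop("label intervals must have end > start", call. = FALSE)
    }
    intervals[, 1] <- pmax(intervals[, 1], 0)
    intervals[, 2] <- pmin(intervals[, 2], total_duration)
    intervals <- intervals[intervals[, 2] > intervals[, 1], , drop = FALSE]
    intervals <- merge_intervals(intervals)
  }
  colnames(intervals) <- c("start", "end")
  structure(list(intervals = intervals, total_duration = total_duration),
            class = "label_track")
}

#' @export
print.label_track <- function(x, ...) {
  cat(sprintf("<label_track: %d speech interval(s), %.3f s speech of %.3f s>\n",
              nrow(x$intervals), speech_time(x), x$total_duration))
  invisible(x)
}

#' Total labeled speech time in seconds
#' @param labels A [label_track].
#' @export
speech_time <- function(labels) {
  if (nrow(labels$intervals) == 0) return(0)
  sum(labels$intervals[, 2] - labels$intervals[, 1])
}

merge_intervals <- function(m) {
  if (nrow(m) <= 1) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1] <= out[k, 2]) {
      out[k, 2] <- max(out[k, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

#' Read a tab-separated label file
#'
#' Parses an Audacity-style label track: one line per interval,
#' `start<TAB>end<TAB>label`, times in seconds. Lines labeled `speech` define
#' the speech spans; `nonspeech` lines are permitted and ignored. Intervals
#' are clipped to the recording duration and overlaps merged.
#'
#' @param path Path to a UTF-8 TSV label file.
#' @param total_duration Recording duration in seconds.
#' @return A [label_track].
#' @export
read_labels <- function(path, total_duration) {
  if (!file.exists(path)) {
    stop("cannot read label file (no such file): ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  rows <- matrix(numeric(0), ncol = 2)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop(sprintf("label file %s line %d: expected start<TAB>end<TAB>label",
                   path, lineno[i]), call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(parts[1]))
    e <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("label file %s line %d: non-numeric start/end",
                   path, lineno[i]), call. = FALSE)
    }
    if (e <= s) {
      stop(sprintf("label file %s line %d: end (%g) <= start (%g)",
                   path, lineno[i], e, s), call. = FALSE)
    }
    lab <- trimws(parts[3])
    if (identical(lab, "speech")) rows <- rbind(rows, c(s, e))
  }
  label_track(rows, total_duration)
}

#' Write a label track as TSV
#'
#' @param labels A [label_track].
#' @param path Output path.
#' @param digits Decimal places for times (default 6, minimum 3).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, digits = 6) {
  digits <- max(3L, as.integer(digits))
  fmt <- sprintf("%%.%df\t%%.%df\tspeech", digits, digits)
  lines <- character(0)
  if (nrow(labels$intervals) > 0) {
    lines <- sprintf(fmt, labels$intervals[, 1], labels$intervals[, 2])
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Rasterize labels onto a frame grid
#'
#' Frame j is marked speech (1) iff the frame's centre time falls inside a
#' labeled speech interval (intervals treated as half-open `[start, end)`).
#'
#' @param labels A [label_track].
#' @param grid A [frame_grid] covering the labeled duration.
#' @return Integer vector of 0/1 of length `grid$n_frames`.
#' @export
labels_to_frames <- function(labels, grid) {
  centers <- frame_centers(grid)
  out <- integer(grid$n_frames)
  iv <- labels$intervals
  for (i in seq_len(nrow(iv))) {
    out[centers >= iv[i, 1] & centers < iv[i, 2]] <- 1L
  }
  out
}

#' Convert a per-frame binary sequence back to labeled intervals
#'
#' Inverse of [labels_to_frames] up to one hop of boundary quantization:
#' maximal runs of speech frames become intervals spanning from the first
#' frame's start to the last frame's end.
#'
#' @param frames Integer 0/1 vector.
#' @param grid The [frame_grid] the frames live on.
#' @return A [label_track].
#' @export
frames_to_labels <- function(frames, grid) {
  stopifnot(length(frames) == grid$n_frames)
  total <- (grid$n_frames - 1L) * grid$hop + grid$frame_length
  r <- rle(as.integer(frames))
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  sel <- r$values == 1L
  if (!any(sel)) return(label_track(NULL, total))
  s <- (starts_idx[sel] - 1L) * grid$hop
  e <- (ends_idx[sel] - 1L) * grid$hop + grid$frame_length
  label_track(cbind(s, pmin(e, total)), total)
}
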