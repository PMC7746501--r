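#' Frame-level scoring of a decision track against ground truth
#'
#' Computes the pooled frame agreement (matching frames over total frames)
#' together with recall (correctly detected speech frames over true speech
#' frames), precision, and the underlying counts.
#'
#' @param pred A `decision_track` or 0/1 integer vector of predictions.
#' @param truth 0/1 integer vector of ground truth, same length.
#' @return List with `agreement`, `recall`, `precision` (fractions, `NA`
#'   where undefined) and `counts` (named integer vector: `correct`,
#'   `total`, `tp`, `fp`, `fn`, `tn`).
#' @export
frame_accuracy <- function(pred, truth) {
  p <- if (inherits(pred, "decision_track")) pred$decisions else
    as.integer(pred)
  t <- as.integer(truth)
  if (length(p) != length(t)) {
    stop("prediction and truth lengths differ (", length(p), " vs ",
         length(t), ")", call. = FALSE)
  }
  tp <- sum(p == 1L & t == 1L)
  fp <- sum(p == 1L & t == 0L)
  fn <- sum(p == 0L & t == 1L)
  tn <- sum(p == 0L & t == 0L)
  total <- length(p)
  correct <- tp + tn
  list(agreement = correct / total,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       counts = c(correct = correct, total = total,
                  tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Phonation ratio
#'
#' Fraction of frames classified as speech over the monitoring period — the
#' core dosimetry statistic for phonation habits.
#'
#' @param track A `decision_track` or 0/1 integer vector.
#' @return A fraction in [0, 1].
#' @export
phonation_ratio <- function(track) {
  d <- if (inherits(track, "decision_track")) track$decisions else
    as.integer(track)
  if (length(d) == 0L) stop("empty decision track", call. = FALSE)
  mean(d)
}

#' Phonation ratio over time
#'
#' Tracks the phonation ratio as a trajectory: in `cumulative` mode the
#' ratio over `[0, t]` at every frame, in `sliding` mode the ratio over the
#' trailing `window` seconds (shorter near the start, where the window is
#' truncated at 0). A sustained nonspeech gap drives the sliding ratio
#' toward zero, which makes breaks in voice use visible.
#'
#' @param track A `decision_track`.
#' @param mode `"sliding"` (default) or `"cumulative"`.
#' @param window Sliding-window length in seconds (default 60); must cover
#'   at least one frame.
#' @return Data frame with columns `time` (frame end time, s) and `ratio`.
#' @export
ratio_over_time <- function(track, mode = c("sliding", "cumulative"),
                            window = 60) {
  mode <- match.arg(mode)
  d <- track$decisions
  n <- length(d)
  grid <- track$grid
  times <- (seq_len(n) - 1L) * grid$hop + grid$frame_length
  cs <- cumsum(d)
  if (mode == "cumulative") {
    ratio <- cs / seq_len(n)
  } else {
    w <- floor(window / grid$hop)
    if (w < 1L) stop("window shorter than one frame", call. = FALSE)
    lo <- pmax(seq_len(n) - w, 0L)
    lead <- numeric(n)
    lead[lo > 0L] <- cs[lo[lo > 0L]]
    ratio <- (cs - lead) / (seq_len(n) - lo)
  }
  data.frame(time = times, ratio = ratio)
}

#' Segment a decision track into alternating speech/nonspeech runs
#'
#' Maximal runs of identical decisions become time segments (duration = run
#' length times hop); consecutive segments alternate kinds and tile the
#' track without gaps.
#'
#' @param track A `decision_track`.
#' @return Data frame with columns `start`, `end` (seconds) and `kind`
#'   (`"speech"`/`"nonspeech"`).
#' @export
to_segments <- function(track) {
  d <- track$decisions
  if (length(d) == 0L) stop("empty decision track", call. = FALSE)
  hop <- track$grid$hop
  r <- rle(d)
  ends <- cumsum(r$lengths) * hop
  starts <- ends - r$lengths * hop
  data.frame(start = starts, end = ends,
             kind = ifelse(r$values == 1L, "speech", "nonspeech"),
             stringsAsFactors = FALSE)
}

#' Default log-spaced duration bins
#'
#' Ten bins per decade over [0.032, 1000] seconds.
#' @export
log_duration_bins <- function() {
  10^seq(log10(0.032), log10(1000), by = 0.1)
}

#' Log-binned segment-duration histogram
#'
#' Counts segment durations into left-closed, right-open bins, separately
#' for speech and nonspeech. Durations outside all bins fall into flagged
#' underflow/overflow rows; totals are conserved.
#'
#' @param segments Segment data frame from [to_segments].
#' @param bins Strictly increasing bin edges in seconds.
#' @return Data frame with `bin_low`, `bin_high`, `kind`, `count`; overflow
#'   rows carry infinite edges.
#' @export
duration_histogram <- function(segments, bins = log_duration_bins()) {
  if (any(diff(bins) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  durations <- segments$end - segments$start
  out <- NULL
  for (kind in c("speech", "nonspeech")) {
    dk <- durations[segments$kind == kind]
    idx <- findInterval(dk, bins, left.open = FALSE)  # [low, high)
    under <- sum(idx == 0L)
    over <- sum(idx == length(bins))
    counts <- tabulate(idx[idx > 0L & idx < length(bins)],
                       nbins = length(bins) - 1L)
    rows <- data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
                       kind = kind, count = counts,
                       stringsAsFactors = FALSE)
    if (under > 0) {
      rows <- rbind(data.frame(bin_low = -Inf, bin_high = bins[1],
                               kind = kind, count = under), rows)
      warning("segment duration(s) below histogram range", call. = FALSE)
    }
    if (over > 0) {
      rows <- rbind(rows, data.frame(bin_low = bins[length(bins)],
                                     bin_high = Inf, kind = kind,
                                     count = over))
      warning("segment duration(s) above histogram range", call. = FALSE)
    }
    out <- rbind(out, rows)
  }
  out
}

#' Assemble a phonation report
#'
#' Bundles the dosimetry outputs for a monitoring session: overall phonation
#' ratio, ratio-over-time trajectory, the alternating speech/nonspeech
#' segment list, the log-binned duration histogram, and (when ground truth
#' is supplied) the frame-accuracy summary.
#'
#' @param track A `decision_track`.
#' @param truth Optional 0/1 ground-truth frame vector.
#' @param ratio_mode,window Passed to [ratio_over_time].
#' @param bins Passed to [duration_histogram].
#' @return A `phonation_report` object.
#' @export
phonation_report <- function(track, truth = NULL,
                             ratio_mode = "sliding", window = 60,
                             bins = log_duration_bins()) {
  segs <- to_segments(track)
  rep <- list(
    overall_ratio = phonation_ratio(track),
    ratio_series = ratio_over_time(track, mode = ratio_mode, window = window),
    segments = segs,
    duration_histogram = suppressWarnings(duration_histogram(segs, bins)),
    accuracy = if (!is.null(truth)) frame_accuracy(track, truth) else NULL
  )
  structure(rep, class = "phonation_report")
}

#' @export
print.phonation_report <- function(x, ...) {
  cat(sprintf("Phonation report\n  phonation ratio: %.1f%%\n",
              100 * x$overall_ratio))
  cat(sprintf("  segments: %d speech, %d nonspeech\n",
              sum(x$segments$kind == "speech"),
              sum(x$segments$kind == "nonspeech")))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  frame agreement: %.1f%% (%d/%d)\n",
                100 * x$accuracy$agreement,
                x$accuracy$counts[["correct"]],
                x$accuracy$counts[["total"]]))
  }
  invisible(x)
}

#' Export a decision track's speech segments as a label TSV
#'
#' @param track A `decision_track`.
#' @param path Output path.
#' @export
segments_to_labels <- function(track, path) {
  lab <- frames_to_labels(track$decisions, track$grid)
  write_labels(lab, path)
}
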