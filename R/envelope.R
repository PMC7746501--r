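#' Per-frame energy envelope
#'
#' The detection feature: the mean squared amplitude (power) of each analysis
#' frame under a rectangular window. Using the mean rather than the sum makes
#' the bias term of the adaptive threshold independent of frame length.
#'
#' @param signal An [audio_signal].
#' @param grid A [frame_grid]; defaults to non-overlapping 32 ms frames on
#'   the signal.
#' @return An `envelope_series` object: list with `values` (non-negative
#'   numeric, one per frame) and `grid`.
#' @export
compute_envelope <- function(signal, grid = frame_grid(signal)) {
  if (grid$n_frames < 1L) {
    stop("signal shorter than one frame: empty envelope", call. = FALSE)
  }
  x2 <- signal$samples^2
  starts <- (seq_len(grid$n_frames) - 1L) * grid$hop_samples
  if (grid$hop_samples == grid$frame_samples) {
    n_used <- grid$n_frames * grid$frame_samples
    vals <- colMeans(matrix(x2[seq_len(n_used)], nrow = grid$frame_samples))
  } else {
    cs <- c(0, cumsum(x2))
    vals <- (cs[starts + grid$frame_samples + 1L] - cs[starts + 1L]) /
      grid$frame_samples
  }
  envelope_series(vals, grid)
}

#' @rdname compute_envelope
#' @param values Non-negative per-frame energies.
#' @export
envelope_series <- function(values, grid) {
  values <- as.numeric(values)
  if (length(values) != grid$n_frames) {
    stop("envelope length must equal grid$n_frames", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < -1e-15)) {
    stop("envelope values must be finite and non-negative", call. = FALSE)
  }
  structure(list(values = pmax(values, 0), grid = grid),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series: %d frames, energy range [%.3g, %.3g]>\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Adaptive-threshold coefficients
#'
#' The five fitted parameters of the detector: four weights on the energy
#' envelope of the current frame (`a[1]`, i = 0) and the three preceding
#' frames (`a[2:4]`, i = 1..3), plus a bias `b` in energy units. The
#' per-frame threshold is
#' \deqn{AT_j = \sum_{i=0}^{3} a_i \hat{E}_{j-i} + b,}
#' with missing (pre-signal) energies taken as zero.
#'
#' @param a Numeric vector of exactly 4 weights.
#' @param b Single numeric bias.
#' @return An `at_coefficients` object.
#' @export
at_coefficients <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != 4L || length(b) != 1L || any(!is.finite(c(a, b)))) {
    stop("need exactly 4 finite weights and 1 finite bias", call. = FALSE)
  }
  structure(list(a = a, b = b), class = "at_coefficients")
}

#' @export
print.at_coefficients <- function(x, ...) {
  cat(sprintf("<at_coefficients: a = (%s), b = %.6g>\n",
              paste(sprintf("%.6g", x$a), collapse = ", "), x$b))
  invisible(x)
}

#' Write/read coefficients as a flat key-value file
#'
#' Plain-text serialization `a0`..`a3`, `b`, one `key = value` per line.
#'
#' @param coef An [at_coefficients].
#' @param path File path.
#' @return `write_coefficients`: `path` invisibly; `read_coefficients`: an
#'   [at_coefficients].
#' @export
write_coefficients <- function(coef, path) {
  keys <- c("a0", "a1", "a2", "a3", "b")
  vals <- c(coef$a, coef$b)
  writeLines(sprintf("%s = %.17g", keys, vals), path)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  kv <- read_keyvals(path)
  need <- c("a0", "a1", "a2", "a3", "b")
  if (!all(need %in% names(kv))) {
    stop("coefficient file must define a0..a3 and b: ", path, call. = FALSE)
  }
  v <- as.numeric(kv[need])
  at_coefficients(v[1:4], v[5])
}

# Flat "key = value" parser shared by coefficient and run-config files.
read_keyvals <- function(path) {
  if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop("malformed key-value line: ", ln, call. = FALSE)
    }
    kv[m[2]] <- trimws(m[3])
  }
  kv
}

#' Per-frame adaptive threshold
#'
#' Evaluates the threshold \eqn{AT_j = \sum_{i} a_i \hat{E}_{j-i} + b} at one
#' frame index or over the whole envelope.
#'
#' @param env An [compute_envelope()] result.
#' @param coef An [at_coefficients].
#' @param j Frame index (1-based). If `NULL` (default) the full threshold
#'   sequence is returned.
#' @param include_current Include the current frame's energy term (i = 0) in
#'   the sum (default TRUE). When FALSE the threshold depends only on the
#'   three preceding frames.
#' @return Numeric threshold value(s).
#' @export
adaptive_threshold <- function(env, coef, j = NULL, include_current = TRUE) {
  at <- threshold_series(env$values, coef, include_current)
  if (is.null(j)) return(at)
  if (any(j < 1L | j > length(at))) {
    stop("frame index out of range", call. = FALSE)
  }
  at[j]
}

# Vectorized threshold over a raw energy vector; pre-signal lags are zero.
threshold_series <- function(e, coef, include_current = TRUE) {
  n <- length(e)
  at <- rep(coef$b, n)
  lag0 <- if (include_current) 0L else 1L
  for (i in seq(lag0, 3L)) {
    w <- coef$a[i + 1L]
    if (w == 0) next
    if (i == 0L) {
      at <- at + w * e
    } else if (i < n) {
      idx <- (i + 1L):n
      at[idx] <- at[idx] + w * e[idx - i]
    }
  }
  at
}

#' Frame-level speech detection
#'
#' Emits 1 (speech) for every frame whose energy strictly exceeds its
#' adaptive threshold, 0 (nonspeech) otherwise; ties resolve to nonspeech.
#'
#' @inheritParams adaptive_threshold
#' @param smooth_window Optional odd integer; when > 1, decisions are
#'   median-filtered with this window as a post-process. Default 1 (off).
#' @return A `decision_track`: list with integer `decisions` (0/1) and
#'   `grid`.
#' @export
detect <- function(env, coef, include_current = TRUE, smooth_window = 1L) {
  if (length(env$values) == 0L) {
    stop("empty envelope", call. = FALSE)
  }
  at <- threshold_series(env$values, coef, include_current)
  d <- as.integer(env$values > at)
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) {
      stop("smooth_window must be odd", call. = FALSE)
    }
    d <- as.integer(stats::runmed(d, smooth_window) > 0.5)
  }
  decision_track(d, env$grid)
}

#' @rdname detect
#' @param decisions Integer 0/1 vector, one decision per frame.
#' @param grid The [frame_grid] the decisions live on.
#' @export
decision_track <- function(decisions, grid) {
  decisions <- as.integer(decisions)
  if (length(decisions) != grid$n_frames) {
    stop("decision length must equal grid$n_frames", call. = FALSE)
  }
  if (any(is.na(decisions)) || any(!decisions %in% c(0L, 1L))) {
    stop("decisions must be 0/1", call. = FALSE)
  }
  structure(list(decisions = decisions, grid = grid),
            class = "decision_track")
}

#' @export
print.decision_track <- function(x, ...) {
  cat(sprintf("<decision_track: %d frames, %.1f%% speech>\n",
              length(x$decisions), 100 * mean(x$decisions)))
  invisible(x)
}

#' Full detection pipeline
#'
#' Optionally enhances the signal with logMMSE noise reduction, then computes
#' the energy envelope and applies the adaptive-threshold detector. With
#' `denoise = FALSE` this is exactly `detect(compute_envelope(signal, grid),
#' coef)`.
#'
#' @param signal An [audio_signal].
#' @param coef An [at_coefficients].
#' @param grid A [frame_grid]; default non-overlapping 32 ms frames.
#' @param denoise Apply logMMSE enhancement before envelope extraction.
#' @param nr_params logMMSE parameters, see [nr_params()].
#' @inheritParams detect
#' @return A `decision_track`.
#' @export
run_pipeline <- function(signal, coef, grid = frame_grid(signal),
                         denoise = FALSE, nr_params = phonodose::nr_params(),
                         include_current = TRUE, smooth_window = 1L) {
  if (denoise) signal <- logmmse(signal, nr_params)
  env <- compute_envelope(signal, grid)
  detect(env, coef, include_current = include_current,
         smooth_window = smooth_window)
}
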