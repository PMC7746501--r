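#' Specification for a synthetic lecture recording
#'
#' Parameters of the generator that emulates a teacher's lecture: alternating
#' voiced utterances (harmonic bursts) and true silences. Utterance and pause
#' lengths are log-normal; the pause distribution's location is shifted so
#' the expected speech duty cycle matches `target_speech_fraction`. Defaults
#' give median 3 s utterances and (at the default fraction of 2/3) median
#' 1.5 s pauses, so most segments are a few seconds long.
#'
#' @param duration Total length in seconds (> 0).
#' @param target_speech_fraction Desired fraction of speech time in (0, 1).
#' @param f0_range Fundamental-frequency interval in Hz (default 100-250,
#'   covering typical adult speech).
#' @param utterance_meanlog,utterance_sdlog Log-normal parameters of
#'   utterance length (seconds).
#' @param pause_sdlog Log-normal spread of pause length; its location is
#'   derived from the target fraction.
#' @param amplitude Peak amplitude in (0, 1].
#' @param seed Integer RNG seed.
#' @return A `speech_synth_spec` list.
#' @export
speech_synth_spec <- function(duration, target_speech_fraction = 2 / 3,
                              f0_range = c(100, 250),
                              utterance_meanlog = log(3),
                              utterance_sdlog = 0.5,
                              pause_sdlog = 0.5,
                              amplitude = 0.3, seed = 1L) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (target_speech_fraction <= 0 || target_speech_fraction >= 1) {
    stop("target_speech_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (amplitude <= 0 || amplitude > 1) {
    stop("amplitude must lie in (0, 1]", call. = FALSE)
  }
  structure(list(duration = duration,
                 target_speech_fraction = target_speech_fraction,
                 f0_range = f0_range,
                 utterance_meanlog = utterance_meanlog,
                 utterance_sdlog = utterance_sdlog,
                 pause_sdlog = pause_sdlog,
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "speech_synth_spec")
}

#' Generate a synthetic lecture with exact ground-truth labels
#'
#' Synthesizes alternating voiced utterances and silences. Each utterance is
#' a harmonic series at a per-utterance random fundamental, with 10 ms linear
#' attack/release ramps and 4 Hz syllabic amplitude modulation; silences are
#' exact zeros, so labels mark the voiced spans with no ambiguity. The
#' schedule is redrawn (bounded retries) until the realized speech fraction
#' is within 5 percentage points of the target.
#'
#' @param spec A [speech_synth_spec].
#' @param rate Sampling rate in Hz (default 16000).
#' @return List with `signal` (an [audio_signal]) and `labels` (a
#'   [label_track] of the voiced spans).
#' @export
make_lecture <- function(spec, rate = 16000) {
  set.seed(spec$seed)
  f <- spec$target_speech_fraction
  # shift the pause location so E[pause]/E[utterance] matches (1-f)/f
  pause_meanlog <- spec$utterance_meanlog + log((1 - f) / f) +
    (spec$utterance_sdlog^2 - spec$pause_sdlog^2) / 2

  draw_schedule <- function() {
    spans <- matrix(numeric(0), ncol = 2)
    t0 <- 0
    while (t0 < spec$duration) {
      u <- stats::rlnorm(1, spec$utterance_meanlog, spec$utterance_sdlog)
      u <- max(u, 0.2)
      e <- min(t0 + u, spec$duration)
      if (e > t0) spans <- rbind(spans, c(t0, e))
      p <- stats::rlnorm(1, pause_meanlog, spec$pause_sdlog)
      t0 <- e + max(p, 0.1)
    }
    spans
  }

  spans <- NULL
  for (try in 1:200) {
    cand <- draw_schedule()
    frac <- sum(cand[, 2] - cand[, 1]) / spec$duration
    if (abs(frac - f) <= 0.05) { spans <- cand; break }
  }
  if (is.null(spans)) {
    stop("could not realize target speech fraction ", f,
         " within 200 schedule draws (infeasible spec?)", call. = FALSE)
  }

  n <- round(spec$duration * rate)
  x <- numeric(n)
  keep <- rep(TRUE, nrow(spans))
  for (k in seq_len(nrow(spans))) {
    i0 <- floor(spans[k, 1] * rate) + 1L
    i1 <- min(n, ceiling(spans[k, 2] * rate))
    m <- i1 - i0 + 1L
    if (m < round(0.02 * rate)) { keep[k] <- FALSE; next }
    tt <- (seq_len(m) - 1L) / rate
    f0 <- stats::runif(1, spec$f0_range[1], spec$f0_range[2])
    n_harm <- max(1L, min(10L, floor(7000 / f0)))
    utt <- numeric(m)
    for (h in seq_len(n_harm)) {
      utt <- utt + sin(2 * pi * h * f0 * tt + stats::runif(1, 0, 2 * pi)) / h
    }
    am <- 0.6 + 0.4 * sin(2 * pi * 4 * tt + stats::runif(1, 0, 2 * pi))
    utt <- utt * am
    ramp_n <- min(m %/% 2L, round(0.010 * rate))       # 10 ms ramps
    env <- rep(1, m)
    if (ramp_n > 0) {
      env[seq_len(ramp_n)] <- seq(0, 1, length.out = ramp_n)
      env[(m - ramp_n + 1L):m] <- seq(1, 0, length.out = ramp_n)
    }
    utt <- utt * env
    utt <- utt / max(abs(utt)) * spec$amplitude
    x[i0:i1] <- utt
    spans[k, ] <- c((i0 - 1L) / rate, i1 / rate)  # snap labels to samples
  }

  list(signal = audio_signal(x, rate),
       labels = label_track(spans[keep, , drop = FALSE], spec$duration))
}

#' Write a deterministic fixture suite
#'
#' Generates and writes: three clean synthetic lectures at different speech
#' fractions (with their exact label tracks), the four noise archetypes, and
#' all clean-by-noise mixtures at the study SNR levels (0, 3 and 5 dB), plus
#' a JSON manifest with per-file MD5 checksums and the achieved SNR of every
#' mixture (measured on the in-memory signals before 16-bit quantization).
#'
#' @param out_dir Writable output directory (created if missing).
#' @param seed Integer master seed; file-level seeds derive from it.
#' @param duration Length of every generated file in seconds (default 30).
#' @param fractions Clean-lecture speech fractions (default 0.45, 0.6, 0.75).
#' @param snrs Mixing SNRs in dB (default 0, 3, 5).
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, duration = 30,
                               fractions = c(0.45, 0.6, 0.75),
                               snrs = c(0, 3, 5)) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  noise_kinds <- c("white", "street", "sharp_speech", "crowd")
  entries <- list()
  cleans <- list()
  noises <- list()

  for (i in seq_along(fractions)) {
    sp <- speech_synth_spec(duration, target_speech_fraction = fractions[i],
                            seed = seed + i)
    lec <- make_lecture(sp)
    stem <- sprintf("clean_f%02d", round(100 * fractions[i]))
    wav <- file.path(out_dir, paste0(stem, ".wav"))
    lab <- file.path(out_dir, paste0(stem, ".labels.tsv"))
    write_wav(lec$signal, wav)
    write_labels(lec$labels, lab)
    cleans[[stem]] <- lec$signal
    entries[[length(entries) + 1L]] <- list(
      file = basename(wav), kind = "clean",
      speech_fraction = fractions[i], labels = basename(lab))
  }

  for (i in seq_along(noise_kinds)) {
    nk <- noise_kinds[i]
    nz <- make_noise(nk, duration, seed = seed + 100L + i)
    # unit-RMS noise peaks can exceed 1; scale for 16-bit storage
    nz <- audio_signal(nz$samples / max(abs(nz$samples)) * 0.9, nz$rate)
    wav <- file.path(out_dir, paste0("noise_", nk, ".wav"))
    write_wav(nz, wav)
    noises[[nk]] <- nz
    entries[[length(entries) + 1L]] <- list(file = basename(wav),
                                            kind = "noise", noise = nk)
  }

  mix_seed <- seed + 1000L
  for (stem in names(cleans)) {
    for (nk in noise_kinds) {
      for (snr in snrs) {
        mix_seed <- mix_seed + 1L
        noisy <- mix_at_snr(cleans[[stem]], noises[[nk]], snr,
                            seed = mix_seed)
        resid <- noisy$samples - cleans[[stem]]$samples
        achieved <- 10 * log10(mean(cleans[[stem]]$samples^2) /
                                 mean(resid^2))
        wav <- file.path(out_dir,
                         sprintf("%s_%s_snr%g.wav", stem, nk, snr))
        write_wav(noisy, wav)
        entries[[length(entries) + 1L]] <- list(
          file = basename(wav), kind = "mixed", clean = stem, noise = nk,
          snr_db = snr, achieved_snr_db = achieved, mix_seed = mix_seed)
      }
    }
  }

  files <- vapply(entries, function(e) e$file, character(1))
  sums <- tools::md5sum(file.path(out_dir, files))
  for (i in seq_along(entries)) entries[[i]]$md5 <- unname(sums[i])
  manifest <- list(seed = seed, duration = duration, entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
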