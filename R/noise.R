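#' Mix noise into a clean signal at an exact SNR
#'
#' Scales the noise so that the whole-signal power ratio matches the
#' requested signal-to-noise ratio exactly: the output is
#' `clean + g * noise` with `g = sqrt(P_clean / (P_noise * 10^(snr_db/10)))`,
#' powers taken as mean squared amplitude over the full signals. When the
#' noise is shorter than the clean signal it is looped; a seed-controlled
#' random offset chooses the noise crop either way.
#'
#' @param clean,noise [audio_signal]s at the same rate.
#' @param snr_db Target SNR in dB (clean power over scaled-noise power).
#' @param seed Integer seed for the noise offset.
#' @return The noisy [audio_signal].
#' @export
mix_at_snr <- function(clean, noise, snr_db, seed = 1L) {
  if (clean$rate != noise$rate) {
    stop("clean and noise must share a sampling rate", call. = FALSE)
  }
  if (!is.finite(snr_db)) stop("snr_db must be finite", call. = FALSE)
  n <- length(clean$samples)
  set.seed(seed)
  nz <- noise$samples
  if (length(nz) < n) {
    reps <- ceiling(n / length(nz)) + 1L
    nz <- rep(nz, reps)
  }
  off <- sample.int(length(nz) - n + 1L, 1L) - 1L
  nz <- nz[(off + 1L):(off + n)]

  p_clean <- mean(clean$samples^2)
  p_noise <- mean(nz^2)
  if (p_clean <= 0 || p_noise <= 0) {
    stop("SNR undefined: zero-power clean or noise signal", call. = FALSE)
  }
  g <- sqrt(p_clean / (p_noise * 10^(snr_db / 10)))
  audio_signal(clean$samples + g * nz, clean$rate)
}

#' Synthetic background-noise archetypes
#'
#' Generates unit-RMS noise of four kinds emulating common classroom
#' backgrounds: `white` (Gaussian), `street` (low-pass filtered below
#' 500 Hz with a slow amplitude drift), `sharp_speech` (sparse band-limited
#' 300-3400 Hz bursts with abrupt onsets), and `crowd` (babble: a
#' superposition of eight independent speech-like harmonic streams).
#' Deterministic for a fixed seed.
#'
#' @param kind One of `"white"`, `"street"`, `"sharp_speech"`, `"crowd"`.
#' @param duration Length in seconds (> 0).
#' @param rate Sampling rate in Hz (default 16000).
#' @param seed Integer RNG seed.
#' @return A unit-RMS [audio_signal].
#' @export
make_noise <- function(kind, duration, rate = 16000, seed = 1L) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  n <- round(duration * rate)
  set.seed(seed)
  x <- switch(kind,
    white = stats::rnorm(n),
    street = {
      bf <- signal::butter(4, 500 / (rate / 2), type = "low")
      y <- signal::filter(bf, stats::rnorm(n))
      # slow drift: random-walk amplitude smoothed to ~0.5 Hz bandwidth
      k <- max(32L, round(rate / 4))
      drift <- stats::filter(stats::rnorm(n), rep(1 / k, k), sides = 1)
      drift[is.na(drift)] <- 0
      as.numeric(y) * (1 + 0.5 * drift / max(abs(drift), 1e-12))
    },
    sharp_speech = {
      y <- numeric(n)
      bf <- signal::butter(4, c(300, 3400) / (rate / 2), type = "pass")
      t0 <- 0
      while (t0 < duration) {
        gap <- stats::rexp(1, rate = 2)        # bursts ~2 per second
        len <- stats::runif(1, 0.05, 0.3)      # 50-300 ms bursts
        i0 <- round((t0 + gap) * rate) + 1L
        i1 <- min(n, i0 + round(len * rate))
        if (i0 < n) {
          burst <- as.numeric(signal::filter(bf, stats::rnorm(i1 - i0 + 1L)))
          y[i0:i1] <- y[i0:i1] + burst          # rectangular gate: abrupt onset
        }
        t0 <- t0 + gap + len
      }
      if (all(y == 0)) y <- as.numeric(signal::filter(bf, stats::rnorm(n)))
      y
    },
    crowd = {
      tt <- seq_len(n) / rate
      y <- numeric(n)
      for (s in 1:8) {
        f0 <- stats::runif(1, 100, 250)
        am_rate <- stats::runif(1, 2, 6)
        phase <- stats::runif(1, 0, 2 * pi)
        stream <- numeric(n)
        for (h in 1:5) {
          stream <- stream + sin(2 * pi * h * f0 * tt +
                                   stats::runif(1, 0, 2 * pi)) / h
        }
        am <- 0.5 + 0.5 * sin(2 * pi * am_rate * tt + phase)
        # independent on/off envelope so streams talk over each other
        gate <- stats::rbinom(ceiling(duration) + 1L, 1L, 0.7)
        gate_t <- gate[pmin(length(gate), floor(tt) + 1L)]
        y <- y + stream * am * gate_t
      }
      y
    },
    stop("unknown noise kind: ", kind, call. = FALSE)
  )
  rms <- sqrt(mean(x^2))
  if (rms <= 0) stop("degenerate noise draw", call. = FALSE)
  audio_signal(x / rms, rate)
}

#' logMMSE noise-reduction parameters
#'
#' Defaults follow standard published practice for the log-spectral-amplitude
#' MMSE estimator: 32 ms Hann analysis frames with 50% overlap, noise PSD
#' initialized from the first 6 frames and recursively updated (smoothing
#' 0.98) in frames judged speech-absent by a likelihood-ratio test,
#' decision-directed a-priori SNR smoothing 0.98 with a -25 dB floor, and a
#' spectral gain floor of 0.1.
#'
#' @param fft_frame Analysis frame length in seconds.
#' @param overlap Frame overlap fraction in (0, 1).
#' @param noise_init_frames Leading frames used to initialize the noise PSD.
#' @param alpha_dd Decision-directed smoothing factor in [0, 1).
#' @param xi_min_db A-priori SNR floor in dB.
#' @param gain_floor Minimal spectral gain in (0, 1]; 1 disables enhancement.
#' @param noise_alpha Noise-PSD update smoothing in speech-absent frames.
#' @param vad_threshold Mean log-likelihood-ratio below which a frame is
#'   treated as speech-absent for noise tracking.
#' @return An `nr_params` list.
#' @export
nr_params <- function(fft_frame = 0.032, overlap = 0.5,
                      noise_init_frames = 6L, alpha_dd = 0.98,
                      xi_min_db = -25, gain_floor = 0.1,
                      noise_alpha = 0.98, vad_threshold = 0.15) {
  if (overlap <= 0 || overlap >= 1) stop("overlap must be in (0,1)",
                                         call. = FALSE)
  if (alpha_dd < 0 || alpha_dd >= 1) stop("alpha_dd must be in [0,1)",
                                          call. = FALSE)
  if (gain_floor <= 0 || gain_floor > 1) stop("gain_floor must be in (0,1]",
                                              call. = FALSE)
  structure(list(fft_frame = fft_frame, overlap = overlap,
                 noise_init_frames = as.integer(noise_init_frames),
                 alpha_dd = alpha_dd, xi_min_db = xi_min_db,
                 gain_floor = gain_floor, noise_alpha = noise_alpha,
                 vad_threshold = vad_threshold),
            class = "nr_params")
}

#' logMMSE speech enhancement
#'
#' Unsupervised single-channel enhancement minimizing the mean-square error
#' of the log spectral amplitude. The signal is analyzed by a Hann-windowed
#' STFT; per frame and frequency bin the a-posteriori SNR gamma and
#' decision-directed a-priori SNR xi give the gain
#' `G = xi/(1+xi) * exp(E1(v)/2)` with `v = xi*gamma/(1+xi)` and `E1` the
#' exponential integral; gains are floored at `params$gain_floor` and the
#' signal resynthesized by overlap-add. The noise power spectrum is
#' initialized from the leading frames and updated recursively in frames a
#' likelihood-ratio test judges speech-absent. Output length equals input
#' length.
#'
#' @param noisy An [audio_signal].
#' @param params An [nr_params()] configuration.
#' @return The enhanced [audio_signal].
#' @export
logmmse <- function(noisy, params = nr_params()) {
  x <- noisy$samples
  rate <- noisy$rate
  flen <- round(params$fft_frame * rate)
  hop <- round(flen * (1 - params$overlap))
  if (length(x) < params$noise_init_frames * flen) {
    stop("signal too short for logMMSE noise initialization", call. = FALSE)
  }
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(flen) - 1) / flen)  # periodic Hann

  # one hop of zero padding at both ends so every true sample is covered by
  # overlapping windows at full weight (wsum = 1): edge samples otherwise sit
  # under a decaying window tail and dividing there amplifies leakage
  n <- length(x)
  n_tot <- n + 2L * hop
  n_frames <- ceiling(max(0L, n_tot - flen) / hop) + 1L
  pad <- (n_frames - 1L) * hop + flen - n - hop
  xp <- c(numeric(hop), x, numeric(pad))

  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(0, flen, n_frames)
  for (k in seq_len(n_frames)) {
    frames[, k] <- xp[(starts[k] + 1L):(starts[k] + flen)] * win
  }
  spec <- stats::mvfft(frames)
  psd <- Re(spec * Conj(spec))

  noise_psd <- rowMeans(psd[, seq_len(min(params$noise_init_frames, n_frames)),
                            drop = FALSE])
  noise_psd <- pmax(noise_psd, 1e-20)

  xi_min <- 10^(params$xi_min_db / 10)
  gmin <- params$gain_floor
  g_prev <- rep(1, flen)
  gamma_prev <- rep(1, flen)
  out_spec <- spec

  for (k in seq_len(n_frames)) {
    gamma <- pmin(psd[, k] / noise_psd, 1e4)
    xi <- params$alpha_dd * g_prev^2 * gamma_prev +
      (1 - params$alpha_dd) * pmax(gamma - 1, 0)
    xi <- pmax(xi, xi_min)
    v <- pmax(xi * gamma / (1 + xi), 1e-10)
    gain <- (xi / (1 + xi)) * exp(0.5 * pracma::expint_E1(v))
    gain <- pmin(gain, 1)
    gain <- pmax(gain, gmin)
    out_spec[, k] <- spec[, k] * gain

    # likelihood-ratio speech-absence test drives noise-PSD tracking
    llr <- mean(gamma * xi / (1 + xi) - log1p(xi))
    if (llr < params$vad_threshold) {
      noise_psd <- params$noise_alpha * noise_psd +
        (1 - params$noise_alpha) * psd[, k]
      noise_psd <- pmax(noise_psd, 1e-20)
    }
    g_prev <- gain
    gamma_prev <- gamma
  }

  rec <- Re(stats::mvfft(out_spec, inverse = TRUE)) / flen
  y <- numeric(length(xp))
  wsum <- numeric(length(xp))
  for (k in seq_len(n_frames)) {
    idx <- (starts[k] + 1L):(starts[k] + flen)
    y[idx] <- y[idx] + rec[, k]
    wsum[idx] <- wsum[idx] + win
  }
  ok <- wsum > 1e-8
  y[ok] <- y[ok] / wsum[ok]
  y[!ok] <- 0
  audio_signal(y[(hop + 1L):(hop + n)], rate)
}
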