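# Shared fixture builders. Everything is generated in code at test time.

# Envelope from raw per-frame values, on a matching non-overlapping grid.
env_from_values <- function(vals) {
  n <- length(vals)
  grid <- frame_grid(n * 0.032, frame_length = 0.032, hop = 0.032)
  stopifnot(grid$n_frames == n)
  envelope_series(vals, grid)
}

# Two-state (speech-like / silence-like) random envelope; caller seeds.
rand_envelope <- function(n_frames) {
  state <- stats::rbinom(1, 1, 0.5)
  vals <- numeric(n_frames)
  for (j in seq_len(n_frames)) {
    if (stats::runif(1) < 0.08) state <- 1L - state
    vals[j] <- if (state == 1L) stats::runif(1, 0.05, 0.3) else
      stats::runif(1, 0, 0.005)
  }
  env_from_values(vals)
}

rand_coef <- function() {
  at_coefficients(stats::runif(4, -2, 2), stats::runif(1, -0.1, 0.1))
}

# Literal per-frame evaluation of the adaptive-threshold rule: the
# independent oracle the vectorized paths are checked against.
at_oracle <- function(e, coef, j) {
  s <- coef$b
  for (i in 0:3) {
    if (j - i >= 1) s <- s + coef$a[i + 1] * e[j - i]
  }
  s
}

detect_oracle <- function(e, coef) {
  vapply(seq_along(e), function(j) as.integer(e[j] > at_oracle(e, coef, j)),
         integer(1))
}

# A 60 s lecture fixture, built once per test run and reused.
local_lecture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- speech_synth_spec(60, target_speech_fraction = 0.5, seed = 11)
      cache <<- make_lecture(sp)
    }
    cache
  }
})
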