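#' Labeled training material for coefficient fitting
#'
#' A collection of utterances, each pairing a per-frame energy envelope with
#' its per-frame ground-truth speech labels.
#'
#' @param utterances List of `list(env = <envelope_series>, truth = <0/1
#'   integer vector>)`, with matching lengths within each utterance.
#' @param provenance Optional identifiers (e.g. window start times) of the
#'   source recording stretches.
#' @return A `training_set` object.
#' @export
training_set <- function(utterances, provenance = NULL) {
  if (length(utterances) < 1L) {
    stop("training set needs at least one utterance", call. = FALSE)
  }
  for (u in utterances) {
    if (!inherits(u$env, "envelope_series")) {
      stop("each utterance needs an envelope_series in $env", call. = FALSE)
    }
    if (length(u$truth) != length(u$env$values)) {
      stop("utterance envelope and truth lengths differ", call. = FALSE)
    }
    if (any(!u$truth %in% c(0L, 1L))) {
      stop("truth must be 0/1", call. = FALSE)
    }
  }
  structure(list(utterances = utterances, provenance = provenance),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  n <- sum(vapply(x$utterances, function(u) length(u$truth), integer(1)))
  cat(sprintf("<training_set: %d utterance(s), %d frames>\n",
              length(x$utterances), n))
  invisible(x)
}

# Pooled lagged-energy design over all utterances. Lags are computed per
# utterance (zero-padded at each utterance start, never across utterances).
# Returns X (n x 4 matrix of E_{j-i}, i = 0..3), e (E_j) and t (truth).
training_design <- function(train) {
  Xs <- lapply(train$utterances, function(u) {
    e <- u$env$values
    n <- length(e)
    lag_of <- function(k) if (k == 0L) e else c(numeric(k), e[seq_len(n - k)])
    cbind(lag_of(0L), lag_of(1L), lag_of(2L), lag_of(3L))
  })
  list(X = do.call(rbind, Xs),
       e = unlist(lapply(train$utterances, function(u) u$env$values)),
       t = unlist(lapply(train$utterances, function(u) as.integer(u$truth))))
}

#' Frame-agreement fitness of a coefficient set
#'
#' Pooled fraction of frames, across all utterances, on which the detector's
#' decision agrees with the ground truth. This is the objective the genetic
#' algorithm maximizes.
#'
#' @param coef An [at_coefficients].
#' @param train A [training_set].
#' @return A number in [0, 1].
#' @export
fitness <- function(coef, train) {
  if (!inherits(train, "training_set")) {
    stop("train must be a training_set", call. = FALSE)
  }
  d <- training_design(train)
  at <- as.numeric(d$X %*% coef$a) + coef$b
  mean(as.integer(d$e > at) == d$t)
}

#' Genetic-algorithm configuration
#'
#' Defaults: real-valued encoding of (a0..a3, b), population 50 evolved for
#' 200 generations, tournament selection of size 3, blend (BLX-0.5) crossover
#' at rate 0.9, per-gene Gaussian mutation at rate 0.2 with standard
#' deviation `mutation_sigma` times the bound width, single-individual
#' elitism. Coefficient bounds assume amplitudes in [-1, 1] (frame energies
#' at most 1): a_i in [-2, 2], b in [-0.1, 0.1].
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate Probability a selected pair is recombined.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_sigma Mutation standard deviation as a fraction of each
#'   gene's bound width.
#' @param coef_bounds 5 x 2 matrix of (low, high) per gene, rows a0..a3, b.
#' @param seed Integer RNG seed; fixes the whole run.
#' @param elitism Number of best individuals copied unchanged (>= 0, <
#'   population_size).
#' @param tournament_size Tournament size for parent selection.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50L, generations = 200L,
                      crossover_rate = 0.9, mutation_rate = 0.2,
                      mutation_sigma = 0.1,
                      coef_bounds = default_coef_bounds(),
                      seed = 1L, elitism = 1L, tournament_size = 3L) {
  coef_bounds <- matrix(as.numeric(coef_bounds), ncol = 2)
  if (population_size < 2L) stop("population_size must be >= 2", call. = FALSE)
  if (generations < 1L) stop("generations must be >= 1", call. = FALSE)
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(coef_bounds) != 5L || any(coef_bounds[, 1] >= coef_bounds[, 2])) {
    stop("coef_bounds must be 5 rows of low < high", call. = FALSE)
  }
  if (elitism < 0L || elitism >= population_size) {
    stop("elitism must be in [0, population_size)", call. = FALSE)
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sigma = mutation_sigma,
                 coef_bounds = coef_bounds,
                 seed = as.integer(seed),
                 elitism = as.integer(elitism),
                 tournament_size = as.integer(tournament_size)),
            class = "ga_config")
}

#' @rdname ga_config
#' @export
default_coef_bounds <- function() {
  cbind(c(-2, -2, -2, -2, -0.1), c(2, 2, 2, 2, 0.1))
}

#' Fit adaptive-threshold coefficients with a genetic algorithm
#'
#' Maximizes pooled frame agreement ([fitness]) over the five detector
#' parameters. Elitism makes the best-so-far fitness trace monotone
#' non-decreasing; the run is fully determined by `cfg$seed`.
#'
#' @param train A [training_set].
#' @param cfg A [ga_config].
#' @return List with `coef` (the best [at_coefficients] ever seen),
#'   `fitness` (its training fitness), and `trace` (best-so-far fitness per
#'   generation).
#' @export
fit_coefficients <- function(train, cfg = ga_config()) {
  if (!inherits(train, "training_set")) {
    stop("train must be a training_set", call. = FALSE)
  }
  d <- training_design(train)
  lo <- cfg$coef_bounds[, 1]
  hi <- cfg$coef_bounds[, 2]
  width <- hi - lo
  np <- cfg$population_size

  eval_fit <- function(v) {
    at <- d$X %*% v[1:4] + v[5]
    mean((d$e > at) == d$t)
  }

  set.seed(cfg$seed)
  pop <- t(replicate(np, stats::runif(5, lo, hi)))
  fit <- apply(pop, 1, eval_fit)

  best_v <- pop[which.max(fit), ]
  best_f <- max(fit)
  trace <- numeric(cfg$generations)

  for (g in seq_len(cfg$generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(cfg$elitism)], , drop = FALSE]

    # tournament selection of parents
    n_off <- np - cfg$elitism
    pick <- function() {
      cand <- sample.int(np, cfg$tournament_size, replace = TRUE)
      cand[which.max(fit[cand])]
    }
    parents <- t(vapply(seq_len(n_off), function(i) pop[pick(), ],
                        numeric(5)))

    # BLX-alpha crossover on consecutive pairs
    alpha <- 0.5
    off <- parents
    i <- 1L
    while (i < n_off) {
      if (stats::runif(1) < cfg$crossover_rate) {
        p1 <- parents[i, ]; p2 <- parents[i + 1L, ]
        lo_g <- pmin(p1, p2) - alpha * abs(p1 - p2)
        hi_g <- pmax(p1, p2) + alpha * abs(p1 - p2)
        off[i, ] <- stats::runif(5, lo_g, hi_g)
        off[i + 1L, ] <- stats::runif(5, lo_g, hi_g)
      }
      i <- i + 2L
    }

    # per-gene Gaussian mutation
    mut <- matrix(stats::runif(n_off * 5) < cfg$mutation_rate, n_off, 5)
    noise <- matrix(stats::rnorm(n_off * 5), n_off, 5) *
      matrix(cfg$mutation_sigma * width, n_off, 5, byrow = TRUE)
    off <- off + mut * noise

    # clip to bounds
    off <- pmin(pmax(off, matrix(lo, n_off, 5, byrow = TRUE)),
                matrix(hi, n_off, 5, byrow = TRUE))

    pop <- rbind(elite, off)
    fit <- apply(pop, 1, eval_fit)
    if (max(fit) > best_f) {
      best_f <- max(fit)
      best_v <- pop[which.max(fit), ]
    }
    trace[g] <- best_f
  }

  list(coef = at_coefficients(best_v[1:4], best_v[5]),
       fitness = best_f, trace = trace)
}

#' Draw disjoint train/test utterance windows from a labeled recording
#'
#' Randomly selects `n_train + n_test` non-overlapping windows of
#' `utterance_length` seconds from the recording (on a fixed lattice of
#' utterance-length slots, so windows can never overlap), computes each
#' window's energy envelope, and rasterizes the labels onto the window's
#' frame grid as ground truth.
#'
#' @param signal An [audio_signal].
#' @param labels A [label_track] for the same recording.
#' @param n_train,n_test Numbers of training and test utterances
#'   (defaults 25 and 5).
#' @param utterance_length Window length in seconds (default 10).
#' @param seed Integer RNG seed.
#' @param frame_length,hop Frame settings for the envelopes (seconds).
#' @return List with `train` and `test` [training_set]s; provenance carries
#'   each window's start time in seconds.
#' @export
split_utterances <- function(signal, labels, n_train = 25L, n_test = 5L,
                             utterance_length = 10, seed = 1L,
                             frame_length = 0.032, hop = frame_length) {
  dur <- duration(signal)
  n_need <- n_train + n_test
  n_slots <- floor(dur / utterance_length)
  if (n_slots < n_need) {
    stop(sprintf(
      "recording too short: %.1f s holds %d windows of %g s, need %d",
      dur, n_slots, utterance_length, n_need), call. = FALSE)
  }
  set.seed(seed)
  slots <- sample.int(n_slots, n_need)
  starts <- (slots - 1L) * utterance_length

  make_utt <- function(w0) {
    i0 <- floor(w0 * signal$rate) + 1L
    i1 <- min(length(signal$samples),
              i0 + round(utterance_length * signal$rate) - 1L)
    sub <- audio_signal(signal$samples[i0:i1], signal$rate)
    grid <- frame_grid(sub, frame_length = frame_length, hop = hop)
    iv <- labels$intervals
    keep <- iv[, 2] > w0 & iv[, 1] < w0 + utterance_length
    sub_iv <- iv[keep, , drop = FALSE]
    if (nrow(sub_iv) > 0) {
      sub_iv[, 1] <- pmax(sub_iv[, 1] - w0, 0)
      sub_iv[, 2] <- pmin(sub_iv[, 2] - w0, utterance_length)
    }
    sub_lab <- label_track(sub_iv, utterance_length)
    list(env = compute_envelope(sub, grid),
         truth = labels_to_frames(sub_lab, grid))
  }

  utts <- lapply(starts, make_utt)
  list(train = training_set(utts[seq_len(n_train)],
                            provenance = starts[seq_len(n_train)]),
       test = training_set(utts[n_train + seq_len(n_test)],
                           provenance = starts[n_train + seq_len(n_test)]))
}
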