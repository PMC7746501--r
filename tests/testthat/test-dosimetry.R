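track_of <- function(d) decision_track(d, frame_grid(length(d) * 0.032))

test_that("frame accuracy returns agreement, recall, precision and counts", {
  d <- c(1L, 1L, 0L, 0L, 1L)
  acc <- frame_accuracy(d, d)
  expect_equal(acc$agreement, 1)
  expect_equal(acc$recall, 1)
  expect_equal(acc$precision, 1)

  pred <- c(1L, 0L, 1L, 0L)
  truth <- c(1L, 1L, 0L, 0L)
  acc <- frame_accuracy(pred, truth)
  expect_equal(acc$agreement, 0.5)
  expect_equal(acc$recall, 0.5)
  expect_equal(acc$precision, 0.5)
  expect_equal(unname(acc$counts[c("tp", "fp", "fn", "tn")]),
               c(1L, 1L, 1L, 1L))

  # agreement is symmetric; recall/precision swap roles
  acc_sw <- frame_accuracy(truth, pred)
  expect_equal(acc_sw$agreement, acc$agreement)

  expect_error(frame_accuracy(c(1L, 0L), c(1L)), "lengths differ")
})

test_that("phonation ratio and its invariants", {
  expect_equal(phonation_ratio(rep(1L, 100)), 1)
  expect_error(phonation_ratio(integer(0)), "empty")

  set.seed(6)
  d <- sample(0:1, 500, replace = TRUE)
  tr <- track_of(d)
  segs <- to_segments(tr)
  speech_dur <- sum(segs$end[segs$kind == "speech"] -
                      segs$start[segs$kind == "speech"])
  total <- length(d) * tr$grid$hop
  expect_equal(phonation_ratio(tr), speech_dur / total, tolerance = 1e-12)
})

test_that("ratio-over-time trajectories behave in both modes", {
  all_speech <- track_of(rep(1L, 200))
  expect_true(all(ratio_over_time(all_speech, "cumulative")$ratio == 1))
  expect_true(all(ratio_over_time(all_speech, "sliding", 1)$ratio == 1))

  # 60 s speech then 60 s silence: sliding 60 s ratio is 0 at the end
  n_min <- round(60 / 0.032)
  tr <- track_of(c(rep(1L, n_min), rep(0L, n_min)))
  r <- ratio_over_time(tr, "sliding", 60)
  expect_equal(r$ratio[nrow(r)], 0)
  # and the cumulative trajectory ends at the overall phonation ratio
  rc <- ratio_over_time(tr, "cumulative")
  expect_equal(rc$ratio[nrow(rc)], phonation_ratio(tr))
  expect_true(all(r$ratio >= 0 & r$ratio <= 1))

  expect_error(ratio_over_time(tr, "sliding", 0.001), "window")
})

test_that("segmentation is run-length encoding on the frame grid", {
  tr <- track_of(c(1L, 1L, 0L, 1L))
  segs <- to_segments(tr)
  expect_equal(segs$start, c(0, 0.064, 0.096))
  expect_equal(segs$end, c(0.064, 0.096, 0.128))
  expect_equal(segs$kind, c("speech", "nonspeech", "speech"))

  tr1 <- track_of(rep(1L, 50))
  segs1 <- to_segments(tr1)
  expect_equal(nrow(segs1), 1)
  expect_equal(segs1$end - segs1$start, 50 * 0.032)

  # naive RLE oracle; alternation and gap-free tiling
  set.seed(7)
  for (rep_i in 1:30) {
    d <- sample(0:1, sample(5:100, 1), replace = TRUE)
    segs <- to_segments(track_of(d))
    want <- list()
    run_start <- 1
    for (j in seq_along(d)[-1]) {
      if (d[j] != d[j - 1]) {
        want[[length(want) + 1]] <- c(run_start, j - 1, d[j - 1])
        run_start <- j
      }
    }
    want[[length(want) + 1]] <- c(run_start, length(d), d[length(d)])
    expect_equal(nrow(segs), length(want))
    for (k in seq_along(want)) {
      expect_equal(segs$start[k], (want[[k]][1] - 1) * 0.032)
      expect_equal(segs$end[k], want[[k]][2] * 0.032)
      expect_equal(segs$kind[k],
                   if (want[[k]][3] == 1) "speech" else "nonspeech")
    }
    expect_true(all(segs$kind[-1] != segs$kind[-nrow(segs)]))
    if (nrow(segs) > 1) {
      expect_equal(segs$start[-1], segs$end[-nrow(segs)])
    }
  }
})

test_that("duration histogram conserves counts and flags overflow", {
  segs <- data.frame(start = 0, end = 5, kind = "speech")
  h <- duration_histogram(segs, bins = c(0.01, 0.1, 1, 10, 100))
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$kind == "speech" & h$bin_low == 1], 1)

  empty <- data.frame(start = numeric(0), end = numeric(0),
                      kind = character(0))
  expect_equal(sum(duration_histogram(empty)$count), 0)

  # left-closed right-open binning: a duration on an edge goes up
  segs_edge <- data.frame(start = 0, end = 1, kind = "nonspeech")
  h <- duration_histogram(segs_edge, bins = c(0.1, 1, 10))
  expect_equal(h$count[h$kind == "nonspeech" & h$bin_low == 1], 1)

  expect_warning(
    duration_histogram(data.frame(start = 0, end = 2000, kind = "speech")),
    "above histogram range")
  expect_error(duration_histogram(segs, bins = c(1, 1, 2)), "increasing")

  set.seed(8)
  for (rep_i in 1:10) {
    n <- sample(1:50, 1)
    durs <- stats::rlnorm(n, 0, 2)
    ends <- cumsum(durs)
    segs <- data.frame(start = ends - durs, end = ends,
                       kind = sample(c("speech", "nonspeech"), n,
                                     replace = TRUE))
    h <- suppressWarnings(duration_histogram(segs))
    expect_equal(sum(h$count), n)
    for (kind in c("speech", "nonspeech")) {
      expect_equal(sum(h$count[h$kind == kind]), sum(segs$kind == kind))
    }
  }
})

test_that("phonation report bundles ratio, segments, histogram and accuracy", {
  set.seed(9)
  d <- sample(0:1, 1000, replace = TRUE, prob = c(0.4, 0.6))
  tr <- track_of(d)
  rep <- phonation_report(tr, truth = d)
  expect_s3_class(rep, "phonation_report")
  expect_equal(rep$overall_ratio, mean(d))
  expect_equal(rep$accuracy$agreement, 1)
  expect_equal(sum(rep$duration_histogram$count), nrow(rep$segments))
  expect_output(print(rep), "Phonation report")
})
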