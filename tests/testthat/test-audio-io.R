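test_that("WAV read handles silence resampling, channel averaging, round trips", {
  # 1 s of 48 kHz silence resampled to 16 kHz stays silent at the new length
  tmp <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_signal(rep(0, 48000), 48000), tmp)
  s <- read_wav(tmp, target_rate = 16000)
  expect_equal(length(s$samples), 16000)
  expect_true(all(s$samples == 0))
  expect_equal(s$rate, 16000)

  # stereo channels x and -x average to zero: written as interleaved frames
  x <- stats::runif(1000, -0.5, 0.5)
  stereo <- as.vector(rbind(x, -x))
  pcm <- as.integer(round(pmin(pmax(stereo, -1), 1) * 32767))
  con <- file(tmp, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(pcm) * 2), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # stereo
  writeBin(16000L, con, size = 4, endian = "little")
  writeBin(64000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(pcm) * 2), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  close(con)
  s2 <- read_wav(tmp)
  # channel cancellation survives quantization to within half a PCM quantum
  expect_lt(max(abs(s2$samples)), 1 / 32767)

  # synthetic utterance survives a 16-bit write/read round trip within 1e-4
  lec <- local_lecture()
  write_wav(lec$signal, tmp)
  s3 <- read_wav(tmp)
  expect_equal(length(s3$samples), length(lec$signal$samples))
  expect_lt(max(abs(s3$samples - lec$signal$samples)), 1e-4)
})

test_that("WAV reader rejects missing, corrupt and empty inputs", {
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), "no such file")
  tmp <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:40), tmp)
  expect_error(read_wav(tmp), "RIFF")
  expect_error(audio_signal(numeric(0), 16000), "empty")
})

test_that("label files parse, merge, clip and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0.0\t1.0\tspeech", "2.0\t3.0\tspeech"), tmp)
  lab <- read_labels(tmp, 5)
  expect_equal(nrow(lab$intervals), 2)
  expect_equal(speech_time(lab), 2.0)

  writeLines(c("0.0\t2.0\tspeech", "1.0\t3.0\tspeech"), tmp)
  lab <- read_labels(tmp, 5)
  expect_equal(unname(lab$intervals[1, ]), c(0, 3))
  expect_equal(nrow(lab$intervals), 1)

  # nonspeech lines ignored; clipping to total duration
  writeLines(c("0.5\t1.0\tspeech", "1.0\t2.0\tnonspeech",
               "4.5\t9.0\tspeech"), tmp)
  lab <- read_labels(tmp, 5)
  expect_equal(unname(lab$intervals[2, ]), c(4.5, 5))

  # format errors carry the line number
  writeLines(c("0.0\t1.0\tspeech", "3.0\t2.0\tspeech"), tmp)
  expect_error(read_labels(tmp, 5), "line 2")
  writeLines("a\tb\tspeech", tmp)
  expect_error(read_labels(tmp, 5), "non-numeric")

  # write/read round trip on 100 random non-overlapping intervals
  set.seed(5)
  starts <- sort(stats::runif(100, 0, 990))
  ends <- starts + stats::runif(100, 0.01, 0.9)
  ends <- pmin(ends, c(starts[-1], 1000))
  keep <- ends > starts
  lab0 <- label_track(cbind(starts[keep], ends[keep]), 1000)
  write_labels(lab0, tmp)
  lab1 <- read_labels(tmp, 1000)
  expect_equal(lab1$intervals, lab0$intervals, tolerance = 1e-6)
})

test_that("frame grid arithmetic matches the 32 ms / 16 kHz design", {
  g <- frame_grid(10)
  expect_equal(g$n_frames, 312L)
  expect_equal(g$frame_samples, 512L)
  expect_equal(g$hop_samples, 512L)
  expect_error(frame_grid(10, hop = 0.064), "hop")
  # grid derived from a signal matches one derived from its duration
  s <- audio_signal(numeric(160000), 16000)
  expect_equal(frame_grid(s)$n_frames, 312L)
})

test_that("labels_to_frames matches brute-force point-in-interval checks", {
  g <- frame_grid(20)
  expect_equal(labels_to_frames(label_track(NULL, 20), g),
               integer(g$n_frames))
  expect_equal(labels_to_frames(label_track(cbind(0, 20), 20), g),
               rep(1L, g$n_frames))

  set.seed(42)
  for (rep_i in 1:25) {
    k <- sample(1:8, 1)
    starts <- sort(stats::runif(k, 0, 18))
    ends <- pmin(starts + stats::runif(k, 0.05, 2), 20)
    lab <- label_track(cbind(starts, ends), 20)
    got <- labels_to_frames(lab, g)
    centers <- (seq_len(g$n_frames) - 1) * g$hop + g$frame_length / 2
    want <- vapply(centers, function(ct) {
      as.integer(any(ct >= lab$intervals[, 1] & ct < lab$intervals[, 2]))
    }, integer(1))
    expect_identical(got, want)
  }
})

test_that("frames_to_labels inverts labels_to_frames within one hop", {
  g <- frame_grid(30)
  set.seed(9)
  for (rep_i in 1:10) {
    k <- sample(2:6, 1)
    starts <- sort(stats::runif(k, 0, 27))
    ends <- pmin(starts + stats::runif(k, 0.3, 2), 30)
    lab <- label_track(cbind(starts, ends), 30)
    fr <- labels_to_frames(lab, g)
    lab2 <- frames_to_labels(fr, g)
    fr2 <- labels_to_frames(lab2, g)
    expect_identical(fr2, fr)
    if (nrow(lab2$intervals) == nrow(lab$intervals)) {
      expect_lt(max(abs(lab2$intervals - lab$intervals)), g$hop + 1e-9)
    }
  }
})
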