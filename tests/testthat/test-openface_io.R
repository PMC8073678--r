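test_that("read_openface_csv parses a toy file and infers the frame rate", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_openface_fixture(p, timestamp = c(0, 0.04),
                         AU12_r = c(0, 1), AU06_r = c(0, 0),
                         extra = data.frame(AU04_r = c(2, 2)))
  s <- read_openface_csv(p, subject_id = "kid1")
  expect_s3_class(s, "au_frame_series")
  expect_length(s, 2)
  expect_equal(s$fps, 25)
  expect_equal(s$au12, c(0, 1))
  expect_equal(s$subject_id, "kid1")
})

test_that("reader tolerates header case/whitespace and ignores extra AU columns", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(" Frame, Timestamp, Confidence, au06_r, AU12_R",
               "1,0.0,0.9,0.1,0.2",
               "2,0.04,0.9,0.1,0.3"), p)
  s <- read_openface_csv(p)
  expect_equal(s$au06, c(0.1, 0.1))
  expect_equal(s$au12, c(0.2, 0.3))
})

test_that("missing required column is a format error naming the column", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_openface_fixture(p, timestamp = c(0, 0.04),
                         AU12_r = c(0, 1), AU06_r = c(0, 0),
                         drop = "AU06_r")
  expect_error(read_openface_csv(p), "AU06_r")
})

test_that("out-of-range intensities are clipped to [0, 5] with a message", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_openface_fixture(p, timestamp = c(0, 0.04, 0.08),
                         AU12_r = c(0, 7.3, 1), AU06_r = c(0, 0, 0))
  expect_message(s <- read_openface_csv(p), "clipped 1")
  expect_equal(s$au12, c(0, 5, 1))
})

test_that("non-finite rows are dropped and empty/disordered inputs error", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_openface_fixture(p, timestamp = c(0, 0.04, 0.08),
                         AU12_r = c(0, NA, 1), AU06_r = c(0, 0, 0))
  expect_message(s <- read_openface_csv(p), "dropped 1")
  expect_length(s, 2)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_openface_fixture(p2, timestamp = c(0, 0.04),
                         AU12_r = c(NA, NA), AU06_r = c(0, 0))
  expect_error(suppressMessages(read_openface_csv(p2)), "no usable rows")

  p3 <- withr::local_tempfile(fileext = ".csv")
  write_openface_fixture(p3, timestamp = c(0.04, 0),
                         AU12_r = c(0, 1), AU06_r = c(0, 0))
  expect_error(read_openface_csv(p3), "strictly increasing")
})

test_that("confidence gate is strict and masks rather than deletes", {
  s <- make_series(au12 = c(1, 1, 1), confidence = c(0.9, 0.7, 0.8))
  g <- apply_confidence_gate(s, 0.75)
  expect_equal(g$valid_mask, c(TRUE, FALSE, TRUE))
  expect_length(g, 3)

  # boundary frame: C == threshold fails the strict gate
  s2 <- au_frame_series("S1", 0, 0.75, 0, 0, fps = 25)
  g2 <- apply_confidence_gate(s2, 0.75)
  expect_false(g2$valid_mask)

  s3 <- make_series(au12 = c(0, 0), confidence = c(1, 1))
  expect_true(all(apply_confidence_gate(s3)$valid_mask))

  expect_error(apply_confidence_gate(s, 1.5), "\\[0, 1\\]")
})

test_that("OpenFace CSV round-trip preserves frames exactly", {
  tr <- sample_subject_trace(group_params(), duration_s = 10, seed = 11,
                             subject_id = "rt")
  p <- withr::local_tempfile(fileext = ".csv")
  write_openface_csv(tr$series, p)
  back <- read_openface_csv(p, subject_id = "rt")
  expect_identical(back$timestamps, tr$series$timestamps)
  expect_identical(back$confidence, tr$series$confidence)
  expect_identical(back$au12, tr$series$au12)
  expect_identical(back$au06, tr$series$au06)
})

test_that("split_at_dropouts keeps an intact recording whole", {
  s <- make_series(au12 = rep(0, 100))
  rec <- split_at_dropouts(apply_confidence_gate(s), max_gap_s = 0.5)
  expect_length(rec$segments, 1)
  expect_equal(rec$usable_seconds, 4.0)
  expect_equal(rec$confidence_pct, 100)
})

test_that("long dropouts split, short ones are bridged by interpolation", {
  conf <- c(rep(0.95, 50), rep(0.5, 25), rep(0.95, 50))
  s <- make_series(au12 = rep(1, 125), confidence = conf)
  rec <- split_at_dropouts(apply_confidence_gate(s), max_gap_s = 0.5)
  expect_length(rec$segments, 2)  # 1.0 s gap > 0.5 s
  expect_equal(rec$usable_seconds, 4.0)
  expect_equal(rec$confidence_pct, 100 * 100 / 125)

  # 5-frame (0.2 s) gap flanked by au12 = 1 and 2: interpolation is
  # strictly inside (1, 2) and monotone.
  au12 <- c(rep(1, 20), rep(0, 5), rep(2, 20))
  conf2 <- c(rep(0.95, 20), rep(0.5, 5), rep(0.95, 20))
  s2 <- make_series(au12 = au12, confidence = conf2)
  rec2 <- split_at_dropouts(apply_confidence_gate(s2), max_gap_s = 0.5)
  expect_length(rec2$segments, 1)
  seg <- rec2$segments[[1]]
  bridged <- seg$au12[21:25]
  expect_true(all(bridged > 1 & bridged < 2))
  expect_true(all(diff(bridged) > 0))
  expect_true(all(seg$valid_mask))
  expect_equal(rec2$usable_seconds, 45 / 25)
})

test_that("a gateless recording yields zero segments, not an error", {
  s <- make_series(au12 = rep(1, 30), confidence = rep(0.5, 30))
  rec <- split_at_dropouts(apply_confidence_gate(s))
  expect_length(rec$segments, 0)
  expect_equal(rec$usable_seconds, 0)
  expect_equal(rec$confidence_pct, 0)
})

test_that("splitting conserves frames and never leaves a long invalid run", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(50:400, 1)
    conf <- ifelse(stats::runif(n) < 0.25, 0.5, 0.95)
    s <- make_series(au12 = stats::runif(n, 0, 3),
                     au06 = stats::runif(n, 0, 3), confidence = conf)
    g <- apply_confidence_gate(s)
    rec <- split_at_dropouts(g, max_gap_s = 0.2)
    kept <- sum(vapply(rec$segments, length, integer(1)))
    expect_lte(kept, n)
    expect_equal(rec$usable_seconds, kept / 25)
    for (seg in rec$segments) {
      runs <- rle(seg$valid_mask)
      bad <- runs$lengths[!runs$values] / seg$fps
      expect_true(all(bad <= 0.2))
      # segments start and end on originally-valid frames
      expect_true(seg$valid_mask[1])
      expect_true(seg$valid_mask[length(seg$valid_mask)])
    }
  }
})

test_that("usable_seconds is invariant under re-splitting a segment", {
  set.seed(32)
  conf <- ifelse(stats::runif(300) < 0.2, 0.5, 0.95)
  s <- make_series(au12 = stats::runif(300, 0, 3), confidence = conf)
  rec <- split_at_dropouts(apply_confidence_gate(s), max_gap_s = 0.3)
  for (seg in rec$segments) {
    again <- split_at_dropouts(seg, max_gap_s = 0.3)
    expect_length(again$segments, 1)
    expect_equal(again$usable_seconds, length(seg) / seg$fps)
  }
})

test_that("write_segments_csv flattens a recording set", {
  s <- make_series(au12 = rep(1, 50))
  rec <- split_at_dropouts(apply_confidence_gate(s))
  p <- withr::local_tempfile(fileext = ".csv")
  write_segments_csv(rec, p)
  flat <- utils::read.csv(p)
  expect_equal(nrow(flat), 50)
  expect_named(flat, c("subject_id", "segment_id", "timestamp",
                       "confidence", "au12", "au06", "valid"))
})
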