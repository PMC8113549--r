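test_that("annotation logs read back validated and in onset order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("recording_id\tlabel\tonset_s\toffset_s",
               "r1\ta\t0.00\t0.10",
               "r1\tb\t0.15\t0.25",
               "r1\tc\t0.30\t0.40"), path)
  rec <- parse_annotations(path)
  expect_s3_class(rec, "song_recording")
  expect_equal(rec$events$label, c("a", "b", "c"))
  expect_equal(rec$events$onset, c(0, 0.15, 0.30))

  # shuffled rows come back sorted
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("recording_id\tlabel\tonset_s\toffset_s",
               "r1\tc\t0.30\t0.40",
               "r1\ta\t0.00\t0.10",
               "r1\tb\t0.15\t0.25"), path2)
  expect_equal(parse_annotations(path2)$events$label, c("a", "b", "c"))
})

test_that("empty and malformed annotation files are handled", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("recording_id\tlabel\tonset_s\toffset_s", empty)
  expect_warning(rec <- parse_annotations(empty), "empty")
  expect_equal(nrow(rec$events), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("recording_id\tlabel\tonset_s\toffset_s",
               "r1\ta\t0.00\t0.10",
               "r1\tb\t0.25\t0.15"), bad)
  expect_error(parse_annotations(bad), "row\\(s\\): 2")

  overlapping <- data.frame(label = c("a", "b"), onset = c(0, 0.05),
                            offset = c(0.10, 0.15))
  expect_error(recording(overlapping), "overlapping")
})

test_that("multi-recording logs split by id; label tracks import", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("recording_id\tlabel\tonset_s\toffset_s",
               "r1\ta\t0.00\t0.10",
               "r2\tb\t0.00\t0.10"), path)
  recs <- parse_annotations(path)
  expect_named(recs, c("r1", "r2"))

  track <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.00\t0.10\ta", "0.15\t0.25\tb"), track)
  rec <- read_label_track(track, recording_id = "t1")
  expect_equal(rec$events$label, c("a", "b"))
})

test_that("annotation write/read round-trips events and pitch", {
  m <- song_model()
  rec <- generate_recording(m, 5, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(rec, path)
  back <- parse_annotations(path)
  expect_equal(back$events$label, rec$events$label)
  expect_equal(back$events$onset, rec$events$onset, tolerance = 1e-6)
  expect_equal(back$events$pitch, rec$events$pitch, tolerance = 1e-3)
})

test_that("bout segmentation splits at the 500 ms gap and partitions events", {
  rec <- rec_from_gaps(c("a", "b", "c", "d", "e"),
                       c(0.05, 0.05, 0.9, 0.05))
  bouts <- segment_bouts(rec)
  expect_length(bouts, 2)
  expect_equal(lengths(lapply(bouts, `[[`, "labels")), c(3, 2))

  one <- segment_bouts(rec_from_gaps(c("a", "b", "c"), c(0.4, 0.49)))
  expect_length(one, 1)

  # concatenated bout sequences reproduce the recording
  expect_equal(unlist(lapply(bouts, `[[`, "labels")), rec$events$label)
  expect_equal(segment_bouts(recording(data.frame(label = character(),
                                                  onset = numeric(),
                                                  offset = numeric()))),
               list())
})

test_that("a long uniform-gap stream splits into singleton bouts", {
  n <- 1000
  rec <- rec_from_gaps(rep("a", n), rep(0.6, n - 1))
  bouts <- segment_bouts(rec)
  expect_length(bouts, n)
  expect_true(all(lengths(lapply(bouts, `[[`, "labels")) == 1))
})

test_that("bout count follows the gap-threshold oracle and is idempotent", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    gaps <- stats::runif(n - 1, 0, 1)
    rec <- rec_from_gaps(sample(letters[1:4], n, replace = TRUE), gaps)
    bouts <- segment_bouts(rec)
    expect_length(bouts, 1 + sum(gaps >= 0.5))
    # segmenting each bout again yields the bout itself
    for (b in bouts) {
      again <- segment_bouts(recording(b$events, "x"))
      expect_length(again, 1)
      expect_equal(again[[1]]$labels, b$labels)
    }
  }
})

test_that("isolated calls are dropped exactly when silent on both sides", {
  # 0.2 s silence on both sides inside a stream -> removed
  ev <- events_from_gaps(c("a", "b", "k", "c", "d"),
                         c(0.05, 0.2, 0.2, 0.05))
  expect_equal(drop_isolated_calls(ev)$label, c("a", "b", "c", "d"))

  # short gap before, long after -> kept (rule requires both sides);
  # the final event is edge-isolated and removed
  ev2 <- events_from_gaps(c("a", "k", "b"), c(0.05, 0.2))
  expect_equal(drop_isolated_calls(ev2)$label, c("a", "k"))

  # lone event: recording edges count as infinite silence
  lone <- events_from_gaps("a", numeric())
  expect_equal(nrow(drop_isolated_calls(lone)), 0)

  # gaps exactly at the threshold do not isolate (strictly "over 100 ms")
  ev3 <- events_from_gaps(c("a", "b", "k", "c", "d"),
                          c(0.05, 0.1, 0.1, 0.05))
  expect_equal(drop_isolated_calls(ev3)$label, c("a", "b", "k", "c", "d"))
})

test_that("call removal never touches events with a close neighbor", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(2:30, 1)
    gaps <- stats::runif(n - 1, 0, 0.3)
    ev <- events_from_gaps(sample(letters[1:3], n, replace = TRUE), gaps)
    kept <- drop_isolated_calls(ev)
    gap_before <- c(Inf, gaps)
    gap_after <- c(gaps, Inf)
    protected <- ev$onset[gap_before <= 0.1 | gap_after <= 0.1]
    expect_true(all(protected %in% kept$onset))
  }
})

test_that("segmentation config enforces threshold ordering and the 5 ms floor", {
  expect_error(segmentation_config(boundary_gap = 0.6), "boundary_gap")
  expect_warning(recording(events_from_gaps(c("a", "b"), 0.001)),
                 "unmerged")
})
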