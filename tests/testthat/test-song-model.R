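test_that("a repeat-free model generates intro runs plus clean motifs", {
  m <- song_model(p_intro = 1, motifs_per_bout = 2)
  rec <- generate_recording(m, 10, seed = 2)
  bouts <- segment_bouts(rec)
  expect_length(bouts, 10)
  for (b in bouts) {
    expect_equal(b$labels, c("i", rep(c("a", "b", "c", "d"), 2)))
  }
})

test_that("generation is deterministic: same seed, byte-identical logs", {
  m <- song_model(insertion_prob = 0.2, omission_prob = c(b = 0.3))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(generate_recording(m, 25, seed = 77), p1)
  write_annotations(generate_recording(m, 25, seed = 77), p2)
  expect_identical(readLines(p1), readLines(p2))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(generate_recording(m, 25, seed = 78), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("intro repeats follow the geometric moment oracle", {
  m <- song_model(p_intro = 0.5)
  rec <- generate_recording(m, 500, seed = 5)
  rs <- repetition_series(segment_bouts(rec), "i")
  se <- sqrt(((1 - 0.5) / 0.5^2) / 500)
  expect_lt(abs(rs$mean - 1), 3 * se)
})

test_that("generated gap structure respects the segmentation thresholds", {
  m <- song_model()
  rec <- generate_recording(m, 30, seed = 8)
  ev <- rec$events
  gaps <- ev$onset[-1] - ev$offset[-nrow(ev)]
  bouts <- segment_bouts(rec)
  expect_length(bouts, 30)
  # within-bout gaps all under the boundary threshold; between-bout over 0.5
  expect_true(all(gaps[gaps < 0.5] <= 0.1))
  expect_equal(sum(gaps >= 0.5), 29)
  expect_true(all(gaps[gaps >= 0.5] > 0.5))
})

test_that("effects return modified copies and respect bounds", {
  m <- song_model(p_intro = 0.9)
  same <- apply_effect(m, song_effect())
  expect_equal(same, m)

  gone <- apply_effect(m, song_effect(omission_delta = c(c = 1)))
  rec <- generate_recording(gone, 20, seed = 3)
  expect_false("c" %in% rec$events$label)
  expect_true("c" %in% generate_recording(m, 20, seed = 3)$events$label)

  infl <- apply_effect(m, song_effect(element = "i", p_rep = 0.5))
  expect_equal(songkit:::repeat_moments(m, "i")$mean, 1 / 9,
               tolerance = 1e-12)
  expect_equal(songkit:::repeat_moments(infl, "i")$mean, 1)
  expect_equal(m$p_intro, 0.9)  # original untouched

  expect_error(song_effect(p_rep = 1.5), "0, 1")
  expect_error(apply_effect(m, song_effect(omission_delta = c(z = 0.1))),
               "motif syllables")
  expect_error(apply_effect(m, song_effect(insertion_delta = 1.5)),
               "\\[0, 1\\]")
})

test_that("pitch-shift effects move the target syllable by the stated SDs", {
  m <- song_model()
  shifted <- apply_effect(m, song_effect(pitch_shift_sd = c(a = 2)))
  sd_a <- m$pitch_cv * m$pitch_mean[["a"]]
  expect_equal(shifted$pitch_mean[["a"]], m$pitch_mean[["a"]] + 2 * sd_a)
  base <- generate_recording(m, 60, seed = 4)$events
  post <- generate_recording(shifted, 60, seed = 5)$events
  res <- pitch_shift_dprime(post$pitch[post$label == "a"],
                            base$pitch[base$label == "a"])
  expect_true(res$significant)
})

test_that("analytic d' follows the shifted-geometric closed form", {
  b <- song_model(p_intro = 0.9)
  expect_equal(expected_repetition_dprime(b, b, "i"), 0)

  i <- apply_effect(b, song_effect(element = "i", p_rep = 0.5))
  expect_equal(expected_repetition_dprime(b, i, "i"),
               sqrt(2) * (1 - 1 / 9) / sqrt(2 + (1 - 0.9) / 0.81),
               tolerance = 1e-12)

  # monotone: lowering p strictly raises d'
  d_vals <- vapply(c(0.8, 0.6, 0.4, 0.2), function(p) {
    expected_repetition_dprime(
      b, apply_effect(b, song_effect(element = "i", p_rep = p)), "i")
  }, numeric(1))
  expect_true(all(diff(d_vals) > 0))

  expect_error(expected_repetition_dprime(b, b, "q"), "no geometric")
})

test_that("repeat-effect calibration hits its target exactly", {
  b <- song_model(p_intro = 0.9)
  for (target in c(0, 0.5, 1, 2, 3)) {
    eff <- calibrate_repeat_effect(b, "i", target)
    achieved <- expected_repetition_dprime(b, apply_effect(b, eff), "i")
    expect_equal(achieved, target, tolerance = 1e-6)
  }
})

test_that("model validation rejects inconsistent structure", {
  expect_error(song_model(intro = "a"), "must not appear")
  expect_error(song_model(gap_within = c(0.02, 0.2)), "0.1")
  expect_error(song_model(gap_between = c(0.3, 0.6)), "0.5")
  expect_error(song_model(omission_prob = c(c = 1.2)), "\\[0, 1\\]")
})
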