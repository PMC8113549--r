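tpl <- motif_template(c("a", "b", "c", "d"), intro = "i")

test_that("interior omissions are syntax alterations with new transitions", {
  rep_ <- classify_syntax_changes(
    tpl,
    baseline_bouts = list(c("i", "a", "b", "c", "d")),
    post_bouts = list(c("i", "a", "b", "d")),
    n_sample = 1
  )
  expect_equal(rep_$pct_bouts_syntax_altered, 100)
  expect_equal(rep_$omissions$syllable, "c")
  expect_true(rep_$omissions$interior)
  expect_true(any(rep_$new_transitions$from == "b" &
                    rep_$new_transitions$to == "d"))
})

test_that("edge omissions are recorded but never syntax alterations", {
  rep_ <- classify_syntax_changes(
    tpl,
    baseline_bouts = list(c("i", "a", "b", "c", "d")),
    post_bouts = list(c("i", "b", "c", "d")),
    n_sample = 1
  )
  expect_equal(rep_$pct_bouts_syntax_altered, 0)
  expect_equal(rep_$pct_bouts_with_omission, 100)
  expect_equal(rep_$omissions$motif_pos, 1L)

  # terminal omission likewise
  rep2 <- classify_syntax_changes(
    tpl,
    baseline_bouts = list(c("i", "a", "b", "c", "d")),
    post_bouts = list(c("i", "a", "b", "c")),
    n_sample = 1
  )
  expect_equal(rep2$pct_bouts_syntax_altered, 0)
  expect_equal(rep2$pct_bouts_with_omission, 100)
})

test_that("novel interior insertions are additions with two new transitions", {
  rep_ <- classify_syntax_changes(
    tpl,
    baseline_bouts = list(c("i", "a", "b", "c", "d")),
    post_bouts = list(c("i", "a", "b", "x9", "c", "d")),
    n_sample = 1
  )
  expect_equal(rep_$pct_bouts_syntax_altered, 100)
  expect_equal(rep_$pct_bouts_with_addition, 100)
  expect_equal(rep_$additions$syllable, "x9")
  tr <- rep_$new_transitions
  expect_true(any(tr$from == "b" & tr$to == "x9"))
  expect_true(any(tr$from == "x9" & tr$to == "c"))
})

test_that("repeat runs collapse before alignment and never read as insertions", {
  rep_ <- classify_syntax_changes(
    tpl,
    baseline_bouts = list(c("i", "a", "b", "c", "d")),
    post_bouts = list(c("i", "i", "i", "a", "b", "b", "b", "c", "d")),
    n_sample = 1
  )
  expect_equal(rep_$pct_bouts_syntax_altered, 0)
  expect_equal(nrow(rep_$additions), 0)
})

test_that("multi-motif bouts align to concatenated templates", {
  rep_ <- classify_syntax_changes(
    tpl,
    baseline_bouts = list(c("i", "a", "b", "c", "d", "a", "b", "c", "d")),
    post_bouts = list(c("i", "a", "b", "c", "d", "a", "b", "d")),
    n_sample = 1
  )
  expect_equal(rep_$pct_bouts_syntax_altered, 100)
  expect_equal(rep_$omissions$syllable, "c")
})

test_that("the alignment engine attains brute-force minimal edit cost", {
  set.seed(17)
  for (case in 1:60) {
    ref <- sample(letters[1:4], sample(2:6, 1), replace = TRUE)
    qry <- sample(letters[1:5], sample(1:6, 1), replace = TRUE)
    al <- songkit:::align_global(qry, ref)
    expect_equal(al$cost, brute_edit_distance(qry, ref))
    # op bookkeeping reconstructs the query length
    n_q <- sum(vapply(al$ops, function(o) o$op != "deletion", logical(1)))
    expect_equal(n_q, length(qry))
  }
})

test_that("unmodified synthetic song yields a clean report", {
  m <- song_model()
  base <- segment_bouts(generate_recording(m, 40, seed = 31))
  post <- segment_bouts(generate_recording(m, 40, seed = 32))
  rep_ <- classify_syntax_changes(tpl, base, post, seed = 1)
  expect_equal(rep_$pct_bouts_syntax_altered, 0)
  expect_equal(rep_$pct_bouts_with_omission, 0)
  expect_equal(rep_$pct_bouts_with_addition, 0)
  expect_equal(nrow(rep_$new_transitions), 0)
})

test_that("bout sampling is seeded, reproducible and respects availability", {
  m <- song_model(omission_prob = c(c = 0.4))
  base <- segment_bouts(generate_recording(song_model(), 40, seed = 33))
  post <- segment_bouts(generate_recording(m, 100, seed = 34))
  r1 <- classify_syntax_changes(tpl, base, post, n_sample = 30, seed = 9)
  r2 <- classify_syntax_changes(tpl, base, post, n_sample = 30, seed = 9)
  expect_identical(r1$bout_flags, r2$bout_flags)
  expect_equal(r1$n_bouts_sampled, 30)
  expect_warning(
    classify_syntax_changes(tpl, base, post[1:10], n_sample = 30, seed = 9),
    "using all")
})

test_that("a known alteration rate is recovered within the binomial interval", {
  # 40 altered bouts (interior omission) among 100
  altered <- replicate(40, c("i", "a", "b", "d"), simplify = FALSE)
  clean <- replicate(60, c("i", "a", "b", "c", "d"), simplify = FALSE)
  post <- sample(c(altered, clean))
  rep_ <- classify_syntax_changes(
    tpl, baseline_bouts = list(c("i", "a", "b", "c", "d")),
    post_bouts = post, n_sample = 30, seed = 4)
  ci <- stats::qbinom(c(0.025, 0.975), 30, 0.4) / 30 * 100
  expect_gte(rep_$pct_bouts_syntax_altered, ci[1])
  expect_lte(rep_$pct_bouts_syntax_altered, ci[2])
})

test_that("percent helper and template validation behave", {
  expect_equal(percent_bouts(c(rep(TRUE, 15), rep(FALSE, 15))), 50)
  expect_equal(percent_bouts(rep(FALSE, 30)), 0)
  expect_error(percent_bouts(logical()), "zero bouts")
  expect_error(motif_template(character()), "non-empty")
  expect_error(motif_template(c("a", "b"), intro = "a"), "disjoint")
})
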