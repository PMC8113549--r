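test_that("transition probabilities come from exhaustive pair tallies", {
  # a b a b then end-of-recording boundary
  tm <- transition_matrix(rec_from_gaps(c("a", "b", "a", "b"),
                                        rep(0.05, 3)))
  expect_equal(unname(tm$probabilities["a", "b"]), 1)
  expect_equal(unname(tm$probabilities["b", "a"]), 0.5)
  expect_equal(unname(tm$probabilities["b", "/"]), 0.5)

  # single-syllable stream normalizes
  tm2 <- transition_matrix(rec_from_gaps(rep("a", 3), rep(0.05, 2)))
  rs <- rowSums(tm2$probabilities)
  expect_true(all(abs(rs[rowSums(tm2$counts) > 0] - 1) < 1e-9))
  # no boundary self-transition
  expect_equal(unname(tm2$counts["/", "/"]), 0L)
})

test_that("gaps over 100 ms insert boundaries and calls are removed first", {
  # 0.15 s gaps are boundaries; middle event is isolated -> removed
  tm <- transition_matrix(rec_from_gaps(c("a", "a", "k", "a", "a"),
                                        c(0.05, 0.15, 0.15, 0.05)))
  expect_false("k" %in% tm$states)
  expect_equal(unname(tm$counts["a", "/"]), 2L)
  expect_error(transition_matrix(list()), "no transitions")
})

test_that("empirical matrix converges to the generating chain", {
  # two-state chain, known kernel
  P <- matrix(c(0.7, 0.3,
                0.2, 0.8), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  set.seed(21)
  n <- 2500
  states <- character(n)
  states[1] <- "a"
  for (i in 2:n) {
    states[i] <- sample(colnames(P), 1, prob = P[states[i - 1], ])
  }
  rec <- rec_from_gaps(states, rep(0.05, n - 1))
  tm <- transition_matrix(rec)
  emp <- tm$probabilities[c("a", "b"), c("a", "b")]
  emp <- emp / rowSums(emp)  # condition on non-boundary successor
  expect_lt(max(abs(emp - P)), 0.05)
})

test_that("rare syllables are pruned across timepoints and counts re-tallied", {
  mk_bouts <- function(seqs) {
    lapply(seqs, function(s) {
      structure(list(labels = s,
                     events = events_from_gaps(s, rep(0.05, length(s) - 1)),
                     recording_id = "r"), class = "song_bout")
    })
  }
  # x present in 1 of 10 bouts
  seqs <- c(replicate(9, c("a", "b"), simplify = FALSE),
            list(c("a", "x", "b")))
  recs <- lapply(seq_along(seqs), function(i) {
    rec_from_gaps(seqs[[i]], rep(0.05, length(seqs[[i]]) - 1),
                  id = paste0("r", i))
  })
  tm <- transition_matrix(recs)
  pruned <- prune_rare_states(tm, mk_bouts(seqs))
  expect_false("x" %in% pruned$states)
  # the a->x->b path re-tallies as a->b, not renormalized away
  expect_equal(unname(pruned$counts["a", "b"]), 10L)

  # all syllables ubiquitous -> identity
  expect_identical(prune_rare_states(tm, mk_bouts(seqs),
                                     min_bout_fraction = 0.05), tm)

  # present in 25% of baseline bouts but 15% of post bouts -> pruned
  base_seqs <- c(replicate(3, c("a", "b"), simplify = FALSE),
                 list(c("a", "x", "b")))
  post_seqs <- c(replicate(17, c("a", "b"), simplify = FALSE),
                 replicate(3, c("a", "x", "b"), simplify = FALSE))
  tm2 <- transition_matrix(lapply(seq_along(base_seqs), function(i) {
    rec_from_gaps(base_seqs[[i]], rep(0.05, length(base_seqs[[i]]) - 1),
                  id = paste0("b", i))
  }))
  pruned2 <- prune_rare_states(tm2, list(baseline = mk_bouts(base_seqs),
                                         post = mk_bouts(post_seqs)))
  expect_false("x" %in% pruned2$states)

  expect_error(prune_rare_states(tm, mk_bouts(seqs), min_bout_fraction = 2),
               "all syllable states")
})

test_that("difference matrices subtract baseline-minus-comparison", {
  tm_b <- transition_matrix(rec_from_gaps(c("a", "b", "a", "b"),
                                          rep(0.05, 3)))
  dm0 <- difference_matrix(tm_b, tm_b)
  expect_true(all(dm0$delta == 0))

  # baseline P(b|a)=1 vs comparison 0.4
  seqs <- list(c("a", "b"), c("a", "b"), c("a", "c"), c("a", "c"),
               c("a", "c"))
  tm_c <- transition_matrix(lapply(seq_along(seqs), function(i) {
    rec_from_gaps(seqs[[i]], 0.05, id = paste0("r", i))
  }))
  dm <- difference_matrix(tm_b, tm_c)
  expect_equal(unname(dm$delta["a", "b"]), 0.6, tolerance = 1e-12)

  # orientation flip and antisymmetry
  dm_f <- difference_matrix(tm_b, tm_c, flip = TRUE)
  expect_equal(dm_f$delta, -dm$delta)
  expect_true(all(dm$delta >= -1 & dm$delta <= 1))

  tm_z <- transition_matrix(rec_from_gaps(c("q", "w"), 0.05))
  expect_error(difference_matrix(tm_b, tm_z), "share no syllable")
})

test_that("matrices write as TSV with the literal boundary label", {
  tm <- transition_matrix(rec_from_gaps(c("a", "b"), 0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(tm, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
  expect_true("/" %in% back$from)
  expect_equal(back[back$from == "a", "b"],
               unname(tm$probabilities["a", "b"]))
})
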