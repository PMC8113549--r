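#' Syllable transition matrix with song-boundary tokens
#'
#' Builds the first-order syllable transition matrix from one or more
#' recordings. Isolated calls are removed first (see
#' [drop_isolated_calls()]); a boundary token `"/"` is then inserted wherever
#' the silent gap exceeds `cfg$boundary_gap` (over 100 ms by default) and at
#' the start and end of every recording. Every adjacent (state, next state)
#' pair is tallied and rows are normalized to probabilities.
#'
#' @param recordings A `song_recording` or list of them.
#' @param cfg A [segmentation_config()].
#' @return An object of class `transition_matrix` with fields `states`
#'   (syllables sorted, `"/"` last), `counts`, `probabilities` (row
#'   stochastic for rows with any count), and `sequences` (the boundary-
#'   annotated token sequences the tally came from, one per recording).
#' @examples
#' ev <- data.frame(label = c("a", "b", "a", "b"),
#'                  onset = c(0, .1, .2, .3) * 1.5,
#'                  offset = c(0, .1, .2, .3) * 1.5 + 0.05)
#' tm <- transition_matrix(recording(ev, "r1"))
#' tm$probabilities["a", "b"]  # 1
#' @export
transition_matrix <- function(recordings, cfg = segmentation_config()) {
  if (inherits(recordings, "song_recording")) recordings <- list(recordings)
  seqs <- lapply(recordings, function(rec) {
    boundary_tokens(rec, cfg)
  })
  seqs <- Filter(function(x) length(x) > 2, seqs)  # "/", syl, "/" minimum
  pairs <- do.call(rbind, lapply(seqs, function(x) {
    cbind(x[-length(x)], x[-1])
  }))
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("no transitions to tally", call. = FALSE)
  }
  pairs <- pairs[!(pairs[, 1] == "/" & pairs[, 2] == "/"), , drop = FALSE]
  new_transition_matrix(pairs, seqs)
}

new_transition_matrix <- function(pairs, sequences) {
  syls <- sort(setdiff(unique(c(pairs[, 1], pairs[, 2])), "/"))
  states <- c(syls, "/")
  counts <- table(factor(pairs[, 1], levels = states),
                  factor(pairs[, 2], levels = states))
  counts <- matrix(as.integer(counts), nrow = length(states),
                   dimnames = list(from = states, to = states))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(
    list(states = states, counts = counts, probabilities = probs,
         sequences = sequences),
    class = "transition_matrix"
  )
}

# token sequence of one recording with "/" at boundaries (> boundary_gap)
# and at the recording edges, after isolated-call removal
boundary_tokens <- function(rec, cfg) {
  ev <- drop_isolated_calls(rec$events, cfg)
  n <- nrow(ev)
  if (n == 0) return(character())
  if (n == 1) return(c("/", ev$label, "/"))
  gaps <- ev$onset[-1] - ev$offset[-n]
  toks <- character(0)
  for (i in seq_len(n)) {
    toks <- c(toks, ev$label[i])
    if (i < n && gaps[i] > cfg$boundary_gap) toks <- c(toks, "/")
  }
  c("/", toks, "/")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("transition_matrix: %d states (%s)\n", length(x$states),
              paste(x$states, collapse = " ")))
  print(round(x$probabilities, digits))
  invisible(x)
}

#' Prune syllables rare across bouts from a transition matrix
#'
#' Syllables present in fewer than `min_bout_fraction` of song bouts at any
#' timepoint are omitted. Counts are re-tallied over the surviving states
#' (pruned tokens are deleted from the underlying sequences before
#' re-tallying), rather than renormalizing rows, so the pruned states' mass
#' is not redistributed arbitrarily.
#'
#' @param tm A [transition_matrix()].
#' @param bouts Either a list of `song_bout` objects (single timepoint) or a
#'   named list of such lists (one element per timepoint).
#' @param min_bout_fraction Presence threshold (default 0.20).
#' @return A pruned `transition_matrix`.
#' @export
prune_rare_states <- function(tm, bouts, min_bout_fraction = 0.20) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (length(bouts) > 0 && inherits(bouts[[1]], "song_bout")) {
    bouts <- list(bouts)
  }
  syls <- setdiff(tm$states, "/")
  keep <- vapply(syls, function(s) {
    all(vapply(bouts, function(tp) {
      mean(vapply(tp, function(b) s %in% b$labels, logical(1))) >=
        min_bout_fraction
    }, logical(1)))
  }, logical(1))
  surviving <- syls[keep]
  if (length(surviving) == 0) {
    stop("pruning removed all syllable states", call. = FALSE)
  }
  if (length(surviving) == length(syls)) return(tm)

  seqs <- lapply(tm$sequences, function(x) {
    x <- x[x %in% c(surviving, "/")]
    # collapse boundary runs left by deletions
    x[c(TRUE, !(x[-1] == "/" & x[-length(x)] == "/"))]
  })
  seqs <- Filter(function(x) length(x) > 2, seqs)
  pairs <- do.call(rbind, lapply(seqs, function(x) {
    cbind(x[-length(x)], x[-1])
  }))
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("pruning removed all transitions", call. = FALSE)
  }
  new_transition_matrix(pairs, seqs)
}

#' Difference between two transition matrices
#'
#' Subtracts the comparison matrix from the baseline matrix entry-wise
#' (default orientation: `baseline - comparison`, so positive entries mark
#' transitions that lost probability after the manipulation). States missing
#' from one matrix are treated as all-zero rows/columns.
#'
#' @param baseline,comparison [transition_matrix()] objects sharing at least
#'   one syllable state.
#' @param flip If `TRUE`, return `comparison - baseline` instead.
#' @return An object of class `difference_matrix` with fields `states` and
#'   `delta` (entries in `[-1, 1]`).
#' @export
difference_matrix <- function(baseline, comparison, flip = FALSE) {
  stopifnot(inherits(baseline, "transition_matrix"),
            inherits(comparison, "transition_matrix"))
  syl_b <- setdiff(baseline$states, "/")
  syl_c <- setdiff(comparison$states, "/")
  if (length(intersect(syl_b, syl_c)) == 0) {
    stop("matrices share no syllable states", call. = FALSE)
  }
  states <- c(sort(union(syl_b, syl_c)), "/")
  expand <- function(tm) {
    m <- matrix(0, length(states), length(states),
                dimnames = list(from = states, to = states))
    m[tm$states, tm$states] <- tm$probabilities
    m
  }
  delta <- expand(baseline) - expand(comparison)
  if (flip) delta <- -delta
  structure(list(states = states, delta = delta),
            class = "difference_matrix")
}

#' @export
print.difference_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("difference_matrix: %d states\n", length(x$states)))
  print(round(x$delta, digits))
  invisible(x)
}

#' Write a transition or difference matrix as TSV
#'
#' The boundary state is written as a literal `"/"` label.
#'
#' @param x A `transition_matrix` or `difference_matrix`.
#' @param path Output path.
#' @param what For transition matrices, `"probabilities"` or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, what = c("probabilities", "counts")) {
  what <- match.arg(what)
  m <- if (inherits(x, "difference_matrix")) x$delta else x[[what]]
  df <- data.frame(from = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
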