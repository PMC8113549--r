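#' Count consecutive repetitions of a vocal element in a bout
#'
#' The per-bout repetition count `n` is the total number of consecutively
#' repeated renditions of a vocal element, not counting the first rendition
#' of each run: a maximal run of `k` back-to-back occurrences contributes
#' `k - 1`. An element may span multiple syllable tokens (e.g. a repeated
#' syllable pair); multi-token runs are tiled greedily left-to-right without
#' overlap.
#'
#' @param bout_labels Character vector of syllable labels in bout order, or a
#'   `song_bout`.
#' @param element Character vector of one or more syllable labels making up
#'   the vocal element.
#' @return Non-negative integer repeat count.
#' @examples
#' count_repeats(c("i", "i", "i", "a", "b", "c", "i", "i"), "i")  # 3
#' count_repeats(c("h", "h2", "h", "h2", "a"), c("h", "h2"))      # 1
#' @export
count_repeats <- function(bout_labels, element) {
  if (inherits(bout_labels, "song_bout")) bout_labels <- bout_labels$labels
  element <- as.character(element)
  if (length(element) == 0) stop("element must be non-empty", call. = FALSE)
  labels <- as.character(bout_labels)
  k <- length(element)
  n <- length(labels)
  total <- 0L
  i <- 1L
  while (i + k - 1L <= n) {
    if (all(labels[i:(i + k - 1L)] == element)) {
      run <- 1L
      j <- i + k
      while (j + k - 1L <= n && all(labels[j:(j + k - 1L)] == element)) {
        run <- run + 1L
        j <- j + k
      }
      total <- total + run - 1L
      i <- j
    } else {
      i <- i + 1L
    }
  }
  total
}

#' Per-bout repetition series for one vocal element
#'
#' Applies [count_repeats()] to every bout of one day/timepoint and attaches
#' the mean and the sample variance (n - 1 denominator) needed by the d'
#' statistic.
#'
#' @param bouts List of `song_bout` objects (or of character label vectors).
#' @param element Vocal element as in [count_repeats()].
#' @param day Timepoint tag (e.g. `"baseline"`, `"post_1mo"`).
#' @return An object of class `repetition_series` with fields `counts`,
#'   `mean`, `variance`, `element`, `day`.
#' @export
repetition_series <- function(bouts, element, day = NA_character_) {
  if (length(bouts) < 2) {
    stop("need at least 2 bouts for a day-level variance", call. = FALSE)
  }
  counts <- vapply(bouts, count_repeats, integer(1), element = element)
  structure(
    list(counts = counts,
         mean = mean(counts),
         variance = stats::var(counts),
         element = as.character(element),
         day = day,
         n_bouts = length(counts)),
    class = "repetition_series"
  )
}

#' @export
print.repetition_series <- function(x, ...) {
  cat(sprintf("repetition_series [%s] element '%s': %d bouts, mean %.3f, var %.3f\n",
              x$day, paste(x$element, collapse = " "), x$n_bouts, x$mean,
              x$variance))
  invisible(x)
}

#' Find vocal elements that repeat
#'
#' Scans bouts for syllables (and adjacent syllable pairs) that were observed
#' to repeat at least `min_repeats` times on at least one occasion, i.e. that
#' occur in a run of length `min_repeats + 1` or more. These are the elements
#' whose repetition is tracked across timepoints.
#'
#' @param bouts List of `song_bout` objects or label vectors.
#' @param min_repeats Minimum per-run repeat count (run length - 1) required
#'   at least once; default 2, i.e. a run of 3 renditions.
#' @param max_element_length Longest multi-token element considered
#'   (default 2: single syllables and adjacent pairs).
#' @return List of character vectors, one per selected element (possibly
#'   empty). Pairs that are trivial repeats of one label (e.g. `c("a","a")`)
#'   are not reported separately.
#' @export
select_repeating_elements <- function(bouts, min_repeats = 2,
                                      max_element_length = 2) {
  seqs <- lapply(bouts, function(b) {
    if (inherits(b, "song_bout")) b$labels else as.character(b)
  })
  candidates <- list()
  singles <- unique(unlist(seqs))
  for (s in singles) candidates[[length(candidates) + 1]] <- s
  if (max_element_length >= 2) {
    pairs <- unique(do.call(rbind, lapply(seqs, function(x) {
      if (length(x) < 2) return(NULL)
      cbind(x[-length(x)], x[-1])
    })))
    if (!is.null(pairs)) {
      pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
      for (i in seq_len(nrow(pairs))) {
        candidates[[length(candidates) + 1]] <- as.character(pairs[i, ])
      }
    }
  }
  selected <- Filter(function(el) {
    any(vapply(seqs, function(x) max_run_repeats(x, el) >= min_repeats,
               logical(1)))
  }, candidates)
  selected
}

# repeat count of the longest run (run length - 1) of element in labels
max_run_repeats <- function(labels, element) {
  k <- length(element)
  n <- length(labels)
  best <- 0L
  i <- 1L
  while (i + k - 1L <= n) {
    if (all(labels[i:(i + k - 1L)] == element)) {
      run <- 1L
      j <- i + k
      while (j + k - 1L <= n && all(labels[j:(j + k - 1L)] == element)) {
        run <- run + 1L
        j <- j + k
      }
      best <- max(best, run - 1L)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  best
}
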