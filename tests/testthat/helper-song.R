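# Build an event table from labels and the silent gaps between them.
# Durations default to 0.05 s; gaps[i] separates event i from event i+1.
events_from_gaps <- function(labels, gaps, dur = 0.05) {
  n <- length(labels)
  stopifnot(length(gaps) == n - 1 || n == 1)
  onsets <- cumsum(c(0, rep(dur, n - 1) + gaps))
  data.frame(label = labels, onset = onsets, offset = onsets + dur,
             stringsAsFactors = FALSE)
}

rec_from_gaps <- function(labels, gaps, id = "r1", ...) {
  recording(events_from_gaps(labels, gaps), recording_id = id, ...)
}

# Independent regular-expression oracle for count_repeats: map each label to
# a single character, count (element)+ runs, repeats = matched length/element
# length - 1 per run.
regex_repeat_oracle <- function(labels, element) {
  alphabet <- unique(c(labels, element))
  stopifnot(length(alphabet) <= 26)
  code <- stats::setNames(letters[seq_along(alphabet)], alphabet)
  s <- paste(code[labels], collapse = "")
  e <- paste(code[element], collapse = "")
  m <- gregexpr(paste0("(?:", e, ")+"), s)[[1]]
  if (m[1] == -1) return(0L)
  lens <- attr(m, "match.length") %/% nchar(e)
  # regex runs can start mid-tiling relative to greedy left-to-right scan
  # only when the element self-overlaps; restrict oracle use accordingly
  sum(lens - 1L)
}

# exhaustive minimal edit distance (unit mismatch/indel) by recursion;
# oracle for the alignment engine on short sequences
brute_edit_distance <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  min(
    brute_edit_distance(a[-1], b[-1]) + (a[1] != b[1]),
    brute_edit_distance(a[-1], b) + 1L,
    brute_edit_distance(a, b[-1]) + 1L
  )
}
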