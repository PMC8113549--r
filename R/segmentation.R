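#' Segmentation configuration
#'
#' Gap thresholds used to validate annotations, split recordings into song
#' bouts, mark song boundaries, and drop isolated calls. Units are seconds.
#' A silent gap is always `next onset - current offset`.
#'
#' @param min_syllable_gap Validation floor for the silence between adjacent
#'   syllables (default 0.005 s, i.e. 5 ms). Events closer than this trigger a
#'   warning, never an automatic merge: the annotations are upstream ground
#'   truth.
#' @param bout_gap Silence at or above which a new song bout starts
#'   (default 0.5 s; within a bout inter-motif intervals are < 500 ms).
#' @param boundary_gap Silence strictly above which a song boundary token
#'   `"/"` is inserted into transition sequences (default 0.1 s).
#' @param call_isolation_gap An event flanked on both sides by silence
#'   strictly longer than this is treated as a call and removed before
#'   transition tallying (default 0.1 s).
#' @return An object of class `segmentation_config`.
#' @examples
#' segmentation_config()
#' segmentation_config(bout_gap = 0.4)
#' @export
segmentation_config <- function(min_syllable_gap = 0.005,
                                bout_gap = 0.5,
                                boundary_gap = 0.1,
                                call_isolation_gap = 0.1) {
  stopifnot(is.numeric(min_syllable_gap), is.numeric(bout_gap),
            is.numeric(boundary_gap), is.numeric(call_isolation_gap))
  if (!(min_syllable_gap > 0 && min_syllable_gap < boundary_gap &&
        boundary_gap <= bout_gap)) {
    stop("require 0 < min_syllable_gap < boundary_gap <= bout_gap",
         call. = FALSE)
  }
  structure(
    list(min_syllable_gap = min_syllable_gap,
         bout_gap = bout_gap,
         boundary_gap = boundary_gap,
         call_isolation_gap = call_isolation_gap),
    class = "segmentation_config"
  )
}

#' @export
print.segmentation_config <- function(x, ...) {
  cat("segmentation_config:",
      sprintf("min_syllable_gap=%gs, bout_gap=%gs, boundary_gap=%gs, call_isolation_gap=%gs",
              x$min_syllable_gap, x$bout_gap, x$boundary_gap,
              x$call_isolation_gap), "\n")
  invisible(x)
}

#' Construct a recording of timed syllable events
#'
#' A recording is an ordered table of labeled syllable events with onset and
#' offset times in seconds, plus optional per-rendition acoustic features
#' (pitch in Hz, Wiener entropy). Events are validated (offset > onset,
#' non-empty labels, no overlaps) and sorted by onset.
#'
#' @param events A data frame with columns `label`, `onset`, `offset` and
#'   optionally `pitch`, `entropy`.
#' @param recording_id Identifier of the recording.
#' @param timepoint Optional experiment-schedule tag (e.g. `"baseline"`,
#'   `"post_2mo"`).
#' @param subject_id Optional subject identifier.
#' @param cfg A [segmentation_config()]; used only for the 5 ms minimum-gap
#'   validation warning.
#' @return An object of class `song_recording` with elements `recording_id`,
#'   `events` (validated, sorted tibble), `timepoint`, `subject_id`.
#' @export
recording <- function(events, recording_id = "recording",
                      timepoint = NA_character_, subject_id = NA_character_,
                      cfg = segmentation_config()) {
  events <- validate_events(events, cfg = cfg)
  structure(
    list(recording_id = recording_id,
         events = events,
         timepoint = timepoint,
         subject_id = subject_id),
    class = "song_recording"
  )
}

#' @export
print.song_recording <- function(x, ...) {
  cat(sprintf("song_recording '%s': %d events", x$recording_id,
              nrow(x$events)))
  if (!is.na(x$timepoint)) cat(sprintf(" [%s]", x$timepoint))
  cat("\n")
  if (nrow(x$events) > 0) {
    cat("  labels:", paste(utils::head(x$events$label, 20), collapse = " "),
        if (nrow(x$events) > 20) "..." else "", "\n")
  }
  invisible(x)
}

validate_events <- function(events, cfg = segmentation_config()) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  required <- c("label", "onset", "offset")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0) {
    stop("events are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events) == 0) {
    out <- tibble::tibble(label = character(), onset = numeric(),
                          offset = numeric())
    return(out)
  }
  events$label <- as.character(events$label)
  events$onset <- as.numeric(events$onset)
  events$offset <- as.numeric(events$offset)

  bad <- which(is.na(events$label) | !nzchar(events$label) |
               is.na(events$onset) | is.na(events$offset) |
               events$onset < 0)
  if (length(bad) > 0) {
    stop("unparseable or invalid annotation row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(events$offset <= events$onset)
  if (length(bad) > 0) {
    stop("offset <= onset on row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  ord <- order(events$onset, events$offset)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL

  if (nrow(events) > 1) {
    gaps <- events$onset[-1] - events$offset[-nrow(events)]
    overlap <- which(gaps < 0)
    if (length(overlap) > 0) {
      stop("overlapping events at sorted row(s): ",
           paste(overlap + 1, collapse = ", "), call. = FALSE)
    }
    close <- which(gaps < cfg$min_syllable_gap)
    if (length(close) > 0) {
      warning(length(close), " inter-syllable gap(s) shorter than ",
              cfg$min_syllable_gap * 1000, " ms left unmerged", call. = FALSE)
    }
  }
  keep <- intersect(c("label", "onset", "offset", "pitch", "entropy"),
                    names(events))
  tibble::as_tibble(events[, keep, drop = FALSE])
}

#' Read a syllable annotation log
#'
#' Reads a delimited text log of syllable annotations (one row per syllable
#' rendition) and returns validated recordings. The default schema expects
#' columns `recording_id`, `label`, `onset_s`, `offset_s` and optionally
#' `pitch_hz`, `entropy`; other dialects are mapped with `schema`.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param schema Named character vector mapping the standard field names
#'   (`recording_id`, `label`, `onset`, `offset`, `pitch`, `entropy`) to the
#'   file's column names. Defaults cover the native dialect.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @param timepoint,subject_id Optional tags attached to every recording.
#' @param cfg A [segmentation_config()] for validation.
#' @return A single `song_recording` if the file contains one recording id,
#'   otherwise a named list of `song_recording` objects (one per id, in order
#'   of first appearance).
#' @seealso [write_annotations()], [read_label_track()]
#' @export
parse_annotations <- function(path, schema = NULL, sep = NULL,
                              timepoint = NA_character_,
                              subject_id = NA_character_,
                              cfg = segmentation_config()) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"", blank.lines.skip = TRUE)
  default_schema <- c(recording_id = "recording_id", label = "label",
                      onset = "onset_s", offset = "offset_s",
                      pitch = "pitch_hz", entropy = "entropy")
  if (!is.null(schema)) default_schema[names(schema)] <- schema
  schema <- default_schema

  if (nrow(df) == 0) {
    warning("empty annotation file: ", path, call. = FALSE)
    return(recording(data.frame(label = character(), onset = numeric(),
                                offset = numeric()),
                     recording_id = "empty", timepoint = timepoint,
                     subject_id = subject_id, cfg = cfg))
  }
  for (field in c("label", "onset", "offset")) {
    if (!schema[[field]] %in% names(df)) {
      stop("cannot resolve required column '", schema[[field]],
           "' for field '", field, "'", call. = FALSE)
    }
  }
  out <- data.frame(label = as.character(df[[schema[["label"]]]]),
                    onset = as.numeric(df[[schema[["onset"]]]]),
                    offset = as.numeric(df[[schema[["offset"]]]]),
                    stringsAsFactors = FALSE)
  if (schema[["pitch"]] %in% names(df)) {
    out$pitch <- as.numeric(df[[schema[["pitch"]]]])
  }
  if (schema[["entropy"]] %in% names(df)) {
    out$entropy <- as.numeric(df[[schema[["entropy"]]]])
  }
  rid <- if (schema[["recording_id"]] %in% names(df)) {
    as.character(df[[schema[["recording_id"]]]])
  } else {
    rep("recording", nrow(out))
  }

  ids <- unique(rid)
  recs <- lapply(ids, function(id) {
    recording(out[rid == id, , drop = FALSE], recording_id = id,
              timepoint = timepoint, subject_id = subject_id, cfg = cfg)
  })
  names(recs) <- ids
  if (length(recs) == 1) recs[[1]] else recs
}

#' Read a two-column label track
#'
#' Imports headerless label-track text (as exported by common audio
#' annotation tools): one line per event, `start<TAB>end<TAB>label`.
#'
#' @inheritParams parse_annotations
#' @param recording_id Identifier to assign to the imported recording.
#' @return A `song_recording`.
#' @export
read_label_track <- function(path, recording_id = "recording",
                             timepoint = NA_character_,
                             subject_id = NA_character_,
                             cfg = segmentation_config()) {
  if (!file.exists(path)) stop("label track not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("onset", "offset", "label"))
  recording(df[, c("label", "onset", "offset")], recording_id = recording_id,
            timepoint = timepoint, subject_id = subject_id, cfg = cfg)
}

#' Write recordings back to an annotation log
#'
#' @param recs A `song_recording` or list of them.
#' @param path Output path; tab-separated with a header row.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(recs, path) {
  if (inherits(recs, "song_recording")) recs <- list(recs)
  rows <- lapply(recs, function(r) {
    ev <- as.data.frame(r$events)
    if (nrow(ev) == 0) return(NULL)
    out <- data.frame(recording_id = r$recording_id,
                      label = ev$label,
                      onset_s = sprintf("%.6f", ev$onset),
                      offset_s = sprintf("%.6f", ev$offset),
                      stringsAsFactors = FALSE)
    if ("pitch" %in% names(ev)) out$pitch_hz <- sprintf("%.4f", ev$pitch)
    out
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Segment a recording into song bouts
#'
#' A new bout starts wherever the silent gap between consecutive events is at
#' least `cfg$bout_gap` (default 500 ms, the inter-motif interval ceiling
#' inside a bout). Bouts partition the events: concatenating the bout label
#' sequences reproduces the recording's sequence.
#'
#' @param rec A `song_recording`.
#' @param cfg A [segmentation_config()].
#' @return A list of `song_bout` objects (possibly empty), each with elements
#'   `events`, `labels`, `recording_id`.
#' @examples
#' ev <- data.frame(label = c("i", "a", "b"),
#'                  onset = c(0, 0.2, 1.0), offset = c(0.1, 0.3, 1.1))
#' rec <- recording(ev, "r1")
#' length(segment_bouts(rec))  # gap of 0.7 s splits into 2 bouts
#' @export
segment_bouts <- function(rec, cfg = segmentation_config()) {
  stopifnot(inherits(rec, "song_recording"))
  ev <- rec$events
  n <- nrow(ev)
  if (n == 0) return(list())
  if (n == 1) {
    idx <- list(1L)
  } else {
    gaps <- ev$onset[-1] - ev$offset[-n]
    bout_id <- cumsum(c(1L, as.integer(gaps >= cfg$bout_gap)))
    idx <- split(seq_len(n), bout_id)
  }
  bouts <- lapply(idx, function(i) {
    structure(list(events = ev[i, , drop = FALSE],
                   labels = ev$label[i],
                   recording_id = rec$recording_id),
              class = "song_bout")
  })
  names(bouts) <- NULL
  bouts
}

#' @export
print.song_bout <- function(x, ...) {
  cat("song_bout:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Remove isolated calls from an event stream
#'
#' Events that are both preceded and followed by silence strictly longer than
#' `cfg$call_isolation_gap` (100 ms by default) likely reflect calls rather
#' than song syllables and are removed before transition tallying. The start
#' and end of the recording count as infinitely long silence, so a lone event
#' is removed.
#'
#' @param events An event table (as in `song_recording$events`) or a
#'   `song_recording`.
#' @param cfg A [segmentation_config()].
#' @return The filtered events table (or recording, matching the input type).
#' @export
drop_isolated_calls <- function(events, cfg = segmentation_config()) {
  if (inherits(events, "song_recording")) {
    rec <- events
    rec$events <- drop_isolated_calls(rec$events, cfg)
    return(rec)
  }
  ev <- events
  n <- nrow(ev)
  if (n == 0) return(ev)
  gap_before <- c(Inf, ev$onset[-1] - ev$offset[-n])
  gap_after <- c(ev$onset[-1] - ev$offset[-n], Inf)
  isolated <- gap_before > cfg$call_isolation_gap &
    gap_after > cfg$call_isolation_gap
  out <- ev[!isolated, , drop = FALSE]
  rownames(out) <- NULL
  out
}
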