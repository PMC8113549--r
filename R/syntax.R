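#' Motif template
#'
#' The baseline song motif as an ordered syllable sequence, plus the set of
#' introductory-element labels (which precede the first motif of a bout and
#' are excluded from motif alignment).
#'
#' @param motif Character vector of syllable labels, in motif order.
#' @param intro Character vector of introductory-element labels; must be
#'   disjoint from the motif.
#' @return An object of class `motif_template`.
#' @export
motif_template <- function(motif, intro = character()) {
  motif <- as.character(motif)
  intro <- as.character(intro)
  if (length(motif) == 0) stop("motif must be non-empty", call. = FALSE)
  if (length(intersect(motif, intro)) > 0) {
    stop("intro labels must be disjoint from the motif", call. = FALSE)
  }
  structure(list(motif = motif, intro = intro), class = "motif_template")
}

#' @export
print.motif_template <- function(x, ...) {
  cat("motif_template:", paste(x$motif, collapse = " "))
  if (length(x$intro)) cat("  (intro:", paste(x$intro, collapse = " "), ")")
  cat("\n")
  invisible(x)
}

# collapse maximal runs of identical tokens to single tokens
collapse_runs <- function(labels) {
  if (length(labels) == 0) return(labels)
  labels[c(TRUE, labels[-1] != labels[-length(labels)])]
}

# Needleman-Wunsch global alignment of a query sequence against a reference,
# unit mismatch/indel cost, match cost 0. Traceback prefers diagonal, then
# deletion (gap in query), then insertion, which places tied deletions
# leftmost. Returns the operation list and total cost.
align_global <- function(query, ref) {
  n <- length(query)
  m <- length(ref)
  D <- matrix(0L, n + 1, m + 1)
  D[1, ] <- 0:m
  D[, 1] <- 0:n
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- D[i, j] + (query[i] != ref[j])
      del <- D[i + 1, j] + 1L   # ref token skipped (deleted from query)
      ins <- D[i, j + 1] + 1L   # query token inserted
      D[i + 1, j + 1] <- min(sub, del, ins)
    }
  }
  ops <- list()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        D[i + 1, j + 1] == D[i, j] + (query[i] != ref[j])) {
      ops[[length(ops) + 1]] <- list(
        op = if (query[i] == ref[j]) "match" else "mismatch",
        ref_pos = j, token = query[i])
      i <- i - 1; j <- j - 1
    } else if (j > 0 && D[i + 1, j + 1] == D[i + 1, j] + 1L) {
      ops[[length(ops) + 1]] <- list(op = "deletion", ref_pos = j,
                                     token = ref[j])
      j <- j - 1
    } else {
      ops[[length(ops) + 1]] <- list(op = "insertion", ref_pos = j,
                                     token = query[i])
      i <- i - 1
    }
  }
  list(ops = rev(ops), cost = D[n + 1, m + 1])
}

# Align a collapsed bout core against m concatenated template copies,
# choosing m (1..ceiling + 1) that minimizes the alignment cost (ties to the
# smaller m). Returns alignment ops annotated with within-motif position.
align_to_template <- function(core, template) {
  L <- length(template)
  m_max <- max(1L, ceiling(length(core) / L) + 1L)
  best <- NULL
  for (m in seq_len(m_max)) {
    al <- align_global(core, rep(template, m))
    if (is.null(best) || al$cost < best$cost) {
      best <- al
      best$n_motifs <- m
    }
  }
  best$ops <- lapply(best$ops, function(o) {
    o$motif_pos <- ((o$ref_pos - 1L) %% L) + 1L
    o$motif_index <- ((o$ref_pos - 1L) %/% L) + 1L
    o
  })
  best$template_length <- L
  best
}

#' Classify syntax changes against a baseline motif template
#'
#' Compares post-manipulation song bouts to the baseline motif and reports
#' syllable omissions, de novo syllable additions, and new syllable
#' transitions. Per bout, repeated-element runs are collapsed to single
#' tokens (repetition is scored separately and must not masquerade as
#' insertion), introductory elements are stripped, and the remaining core is
#' globally aligned to the best-fitting number of concatenated template
#' copies (unit mismatch/indel cost, tied deletions leftmost).
#'
#' Omissions and additions at the first or last motif position are recorded
#' but do not count toward the percentage of bouts with syntax alterations;
#' only interior changes do.
#'
#' @param template A [motif_template()] derived from baseline song.
#' @param baseline_bouts,post_bouts Lists of `song_bout` objects (or label
#'   vectors) for the baseline and comparison timepoints.
#' @param n_sample Number of bouts sampled per timepoint for the percentage
#'   metrics (default 30). If fewer bouts are available all are used, with a
#'   warning.
#' @param seed Seed for the reproducible bout subsample.
#' @return An object of class `syntax_change_report`: `new_transitions`
#'   (data frame of from/to pairs absent from the baseline transition set),
#'   `omissions` and `additions` (data frames with syllable and motif
#'   position), `pct_bouts_syntax_altered`, `pct_bouts_with_omission`,
#'   `pct_bouts_with_addition`, `n_bouts_sampled`, and the per-bout flag
#'   table `bout_flags`.
#' @export
classify_syntax_changes <- function(template, baseline_bouts, post_bouts,
                                    n_sample = 30, seed = NULL) {
  stopifnot(inherits(template, "motif_template"))
  if (length(post_bouts) == 0) stop("no post bouts supplied", call. = FALSE)
  get_labels <- function(b) if (inherits(b, "song_bout")) b$labels else
    as.character(b)
  base_seqs <- lapply(baseline_bouts, get_labels)
  post_seqs <- lapply(post_bouts, get_labels)

  repertoire <- unique(c(unlist(base_seqs), template$motif, template$intro))
  base_pairs <- unique(do.call(rbind, lapply(base_seqs, function(x) {
    x <- collapse_runs(x)
    if (length(x) < 2) return(NULL)
    cbind(x[-length(x)], x[-1])
  })))
  base_pair_keys <- if (is.null(base_pairs)) character() else
    paste(base_pairs[, 1], base_pairs[, 2], sep = "\r")

  idx <- sample_bout_indices(length(post_seqs), n_sample, seed)
  sampled <- post_seqs[idx]

  omissions <- list(); additions <- list(); new_trans <- list()
  flags <- data.frame(bout = idx, altered = FALSE, omission = FALSE,
                      addition = FALSE)
  L <- length(template$motif)
  for (k in seq_along(sampled)) {
    labs <- collapse_runs(sampled[[k]])
    core <- labs[!(labs %in% template$intro)]
    if (length(core) == 0) next
    al <- align_to_template(core, template$motif)
    for (o in al$ops) {
      interior <- o$motif_pos > 1L && o$motif_pos < L
      if (o$op == "deletion") {
        omissions[[length(omissions) + 1]] <-
          data.frame(syllable = o$token, motif_pos = o$motif_pos,
                     interior = interior, bout = idx[k])
        flags$omission[k] <- TRUE
        if (interior) flags$altered[k] <- TRUE
      } else if (o$op == "insertion") {
        novel <- !(o$token %in% repertoire)
        # insertion between motif copies / at the very ends is an edge change
        at_edge <- o$motif_pos == L || o$ref_pos == 0L
        if (novel) {
          additions[[length(additions) + 1]] <-
            data.frame(syllable = o$token, after_motif_pos = o$motif_pos,
                       interior = !at_edge, bout = idx[k])
          flags$addition[k] <- TRUE
          if (!at_edge) flags$altered[k] <- TRUE
        } else if (!at_edge) {
          flags$altered[k] <- TRUE
        }
      } else if (o$op == "mismatch") {
        novel <- !(o$token %in% repertoire)
        omissions[[length(omissions) + 1]] <-
          data.frame(syllable = template$motif[o$motif_pos],
                     motif_pos = o$motif_pos, interior = interior,
                     bout = idx[k])
        flags$omission[k] <- TRUE
        if (novel) {
          additions[[length(additions) + 1]] <-
            data.frame(syllable = o$token, after_motif_pos = o$motif_pos,
                       interior = interior, bout = idx[k])
          flags$addition[k] <- TRUE
        }
        if (interior) flags$altered[k] <- TRUE
      }
    }
    if (length(labs) >= 2) {
      pk <- paste(labs[-length(labs)], labs[-1], sep = "\r")
      new_idx <- which(!(pk %in% base_pair_keys))
      for (t in new_idx) {
        new_trans[[length(new_trans) + 1]] <-
          data.frame(from = labs[t], to = labs[t + 1], bout = idx[k])
      }
    }
  }
  bind0 <- function(lst, proto) {
    if (length(lst) == 0) proto else unique(do.call(rbind, lst))
  }
  structure(
    list(
      new_transitions = bind0(new_trans,
        data.frame(from = character(), to = character(), bout = integer())),
      omissions = bind0(omissions,
        data.frame(syllable = character(), motif_pos = integer(),
                   interior = logical(), bout = integer())),
      additions = bind0(additions,
        data.frame(syllable = character(), after_motif_pos = integer(),
                   interior = logical(), bout = integer())),
      pct_bouts_syntax_altered = percent_bouts(flags$altered),
      pct_bouts_with_omission = percent_bouts(flags$omission),
      pct_bouts_with_addition = percent_bouts(flags$addition),
      n_bouts_sampled = length(sampled),
      bout_flags = flags
    ),
    class = "syntax_change_report"
  )
}

#' @export
print.syntax_change_report <- function(x, ...) {
  cat(sprintf("syntax_change_report over %d bouts:\n", x$n_bouts_sampled))
  cat(sprintf("  %% bouts syntax-altered: %.1f\n", x$pct_bouts_syntax_altered))
  cat(sprintf("  %% bouts with omission:  %.1f\n", x$pct_bouts_with_omission))
  cat(sprintf("  %% bouts with addition:  %.1f\n", x$pct_bouts_with_addition))
  if (nrow(x$new_transitions)) {
    tr <- unique(x$new_transitions[, c("from", "to")])
    cat("  new transitions:",
        paste(sprintf("(%s,%s)", tr$from, tr$to), collapse = " "), "\n")
  }
  invisible(x)
}

#' Percentage of bouts exhibiting a change
#'
#' @param flags Logical vector, one element per sampled bout.
#' @return `100 * mean(flags)`.
#' @export
percent_bouts <- function(flags) {
  if (length(flags) == 0) stop("zero bouts", call. = FALSE)
  100 * mean(as.logical(flags))
}

# seeded uniform subsample without replacement; uses all (with a warning)
# when fewer bouts than requested are available
sample_bout_indices <- function(n_available, n_sample, seed = NULL) {
  if (n_available == 0) stop("zero bouts", call. = FALSE)
  if (n_available <= n_sample) {
    if (n_available < n_sample) {
      warning("only ", n_available, " bouts available; using all",
              call. = FALSE)
    }
    return(seq_len(n_available))
  }
  with_preserved_seed(seed, sort(sample.int(n_available, n_sample)))
}
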