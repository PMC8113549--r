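#' Generative model of annotated zebra finch song
#'
#' Parameterizes a seeded generator of syllable annotation logs with the
#' structure the sequence statistics assume: bouts of repeated introductory
#' notes followed by one or more stereotyped motifs, run-length-distributed
#' syllable repetition, and configurable omission, de novo insertion, and
#' pitch-shift effects.
#'
#' Per-bout repetition counts of a repeat-eligible element follow a shifted
#' geometric law: `repeats = base + Geom(p)` with `Geom` supported on
#' 0, 1, 2, ... (mean `(1-p)/p`). The default `base = 0` is the memoryless
#' repeat/advance model; a positive integer `base` adds a deterministic floor
#' so that arbitrarily large standardized effects remain expressible (a pure
#' geometric bounds the mean/SD ratio at 1 and hence d' below sqrt(2)).
#' The run is drawn once per bout at the element's template position, which
#' keeps the analytic d' of [expected_repetition_dprime()] exact.
#'
#' @param motif Character vector: the stereotyped motif (3-7 syllables
#'   typical).
#' @param intro Introductory-note label.
#' @param p_intro Geometric parameter of the intro repeat distribution.
#' @param repeats Named list of repeat specifications for motif elements, as
#'   built by [repeat_spec()]; keys are the space-joined element tokens. The
#'   intro note is always repeat-eligible with `p_intro`.
#' @param omission_prob Named per-syllable omission probability per motif
#'   rendition (default none).
#' @param insertion_prob Probability that a motif rendition carries one de
#'   novo syllable inserted at a random interior slot.
#' @param motifs_per_bout Integer vector of admissible motif counts per bout,
#'   sampled uniformly (default 2:3).
#' @param syllable_dur Mean and SD (seconds) of syllable durations.
#' @param gap_within Range (seconds) of within-bout silent gaps; must stay
#'   at or below the 100 ms boundary threshold so bouts hold together.
#' @param gap_between Range (seconds) of between-bout gaps; must exceed the
#'   500 ms bout threshold.
#' @param pitch_mean Named vector of per-syllable mean pitch (Hz). Labels
#'   without an entry get a default spread over 450-1000 Hz.
#' @param pitch_cv Rendition-to-rendition pitch coefficient of variation
#'   (fractional; 0.015 emulates the ~1.5% CV of stable adult song).
#' @param novel_prefix Label prefix for de novo inserted syllables; novel
#'   labels always fall outside the baseline repertoire so additions are
#'   detectable by label identity.
#' @return An object of class `song_model`.
#' @seealso [generate_recording()], [apply_effect()],
#'   [expected_repetition_dprime()]
#' @export
song_model <- function(motif = c("a", "b", "c", "d"),
                       intro = "i",
                       p_intro = 0.5,
                       repeats = list(),
                       omission_prob = NULL,
                       insertion_prob = 0,
                       motifs_per_bout = 2:3,
                       syllable_dur = c(mean = 0.08, sd = 0.008),
                       gap_within = c(0.02, 0.08),
                       gap_between = c(0.7, 1.5),
                       pitch_mean = NULL,
                       pitch_cv = 0.015,
                       novel_prefix = "x") {
  motif <- as.character(motif)
  stopifnot(length(motif) >= 1, length(intro) == 1,
            p_intro > 0, p_intro <= 1,
            insertion_prob >= 0, insertion_prob <= 1)
  if (intro %in% motif) stop("intro label must not appear in the motif",
                             call. = FALSE)
  if (gap_within[2] > 0.1) {
    stop("within-bout gaps must stay <= 0.1 s (song-boundary threshold)",
         call. = FALSE)
  }
  if (gap_between[1] <= 0.5) {
    stop("between-bout gaps must exceed 0.5 s (bout threshold)",
         call. = FALSE)
  }
  om <- stats::setNames(rep(0, length(motif)), motif)
  if (!is.null(omission_prob)) {
    if (is.null(names(omission_prob)) ||
        !all(names(omission_prob) %in% motif)) {
      stop("omission_prob must be named by motif syllables", call. = FALSE)
    }
    if (any(omission_prob < 0 | omission_prob > 1)) {
      stop("omission probabilities must lie in [0, 1]", call. = FALSE)
    }
    om[names(omission_prob)] <- omission_prob
  }
  reps <- list()
  reps[[intro]] <- repeat_spec(intro, p = p_intro)
  for (r in repeats) {
    stopifnot(inherits(r, "repeat_spec"))
    reps[[paste(r$element, collapse = " ")]] <- r
  }
  if (is.null(pitch_mean)) {
    labs <- c(intro, motif)
    pitch_mean <- stats::setNames(
      c(450, seq(550, 1000, length.out = length(motif))), labs)
  }
  structure(
    list(motif = motif, intro = intro, p_intro = p_intro,
         repeats = reps, omission_prob = om,
         insertion_prob = insertion_prob,
         motifs_per_bout = as.integer(motifs_per_bout),
         syllable_dur = syllable_dur, gap_within = gap_within,
         gap_between = gap_between, pitch_mean = pitch_mean,
         pitch_cv = pitch_cv, novel_prefix = novel_prefix),
    class = "song_model"
  )
}

#' Repeat-eligibility specification for a vocal element
#'
#' @param element Character vector of one or more syllable tokens.
#' @param p Geometric parameter in (0, 1]; the per-bout repeat count is
#'   `base + Geom(p)` with mean `base + (1-p)/p`.
#' @param base Deterministic repeat floor (non-negative integer, default 0).
#' @return An object of class `repeat_spec`.
#' @export
repeat_spec <- function(element, p, base = 0L) {
  stopifnot(p > 0, p <= 1, base >= 0, base == round(base))
  structure(list(element = as.character(element), p = p,
                 base = as.integer(base)),
            class = "repeat_spec")
}

#' @export
print.song_model <- function(x, ...) {
  cat("song_model: intro", x$intro, "| motif",
      paste(x$motif, collapse = " "), "\n")
  for (r in x$repeats) {
    cat(sprintf("  repeats %s: p=%.3f base=%d\n",
                paste(r$element, collapse = " "), r$p, r$base))
  }
  if (any(x$omission_prob > 0)) {
    op <- x$omission_prob[x$omission_prob > 0]
    cat("  omission:", paste(sprintf("%s=%.2f", names(op), op),
                             collapse = " "), "\n")
  }
  if (x$insertion_prob > 0) {
    cat(sprintf("  insertion: %.2f per motif\n", x$insertion_prob))
  }
  invisible(x)
}

#' Step-change effect on a song model
#'
#' Describes a knockdown- or stimulation-like phenotype as a step change:
#' repeat inflation of one element, per-syllable omission probability
#' increments, an insertion-rate increment, and/or a pitch shift (in SD
#' units) of a target syllable.
#'
#' @param element Element whose repeat distribution changes (required with
#'   `p_rep`/`repeat_base`).
#' @param p_rep New geometric parameter for `element`.
#' @param repeat_base New deterministic repeat floor for `element`.
#' @param omission_delta Named increments to per-syllable omission
#'   probabilities.
#' @param insertion_delta Increment to the per-motif insertion probability.
#' @param pitch_shift_sd Named per-syllable pitch shifts, in units of the
#'   rendition SD (`pitch_cv * pitch_mean`).
#' @return An object of class `song_effect`.
#' @export
song_effect <- function(element = NULL, p_rep = NULL, repeat_base = NULL,
                        omission_delta = NULL, insertion_delta = 0,
                        pitch_shift_sd = NULL) {
  if (!is.null(p_rep) && (p_rep <= 0 || p_rep > 1)) {
    stop("p_rep must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(element = if (is.null(element)) NULL else as.character(element),
         p_rep = p_rep, repeat_base = repeat_base,
         omission_delta = omission_delta,
         insertion_delta = insertion_delta,
         pitch_shift_sd = pitch_shift_sd),
    class = "song_effect"
  )
}

#' Apply an effect to a song model
#'
#' Returns a new model; the input model is unchanged.
#'
#' @param model A [song_model()].
#' @param effect A [song_effect()].
#' @return A modified `song_model`.
#' @export
apply_effect <- function(model, effect) {
  stopifnot(inherits(model, "song_model"), inherits(effect, "song_effect"))
  out <- model
  if (!is.null(effect$element)) {
    key <- paste(effect$element, collapse = " ")
    prev <- out$repeats[[key]]
    p <- if (!is.null(effect$p_rep)) effect$p_rep else
      if (!is.null(prev)) prev$p else 1
    base <- if (!is.null(effect$repeat_base)) effect$repeat_base else
      if (!is.null(prev)) prev$base else 0L
    out$repeats[[key]] <- repeat_spec(effect$element, p = p, base = base)
    if (key == out$intro) out$p_intro <- p
  }
  if (!is.null(effect$omission_delta)) {
    nm <- names(effect$omission_delta)
    if (is.null(nm) || !all(nm %in% out$motif)) {
      stop("omission_delta must be named by motif syllables", call. = FALSE)
    }
    new <- out$omission_prob[nm] + effect$omission_delta
    if (any(new < 0 | new > 1)) {
      stop("omission probability out of [0, 1] after effect", call. = FALSE)
    }
    out$omission_prob[nm] <- new
  }
  if (effect$insertion_delta != 0) {
    new <- out$insertion_prob + effect$insertion_delta
    if (new < 0 || new > 1) {
      stop("insertion probability out of [0, 1] after effect", call. = FALSE)
    }
    out$insertion_prob <- new
  }
  if (!is.null(effect$pitch_shift_sd)) {
    nm <- names(effect$pitch_shift_sd)
    if (is.null(nm) || !all(nm %in% names(out$pitch_mean))) {
      stop("pitch_shift_sd must be named by known syllables", call. = FALSE)
    }
    sd_hz <- out$pitch_cv * out$pitch_mean[nm]
    out$pitch_mean[nm] <- out$pitch_mean[nm] +
      effect$pitch_shift_sd * sd_hz
  }
  out
}

# moments of the shifted-geometric per-bout repeat count of an element
repeat_moments <- function(model, element) {
  key <- paste(as.character(element), collapse = " ")
  spec <- model$repeats[[key]]
  if (is.null(spec)) {
    stop("element '", key, "' has no geometric repeat specification",
         call. = FALSE)
  }
  p <- spec$p
  list(mean = spec$base + (1 - p) / p, var = (1 - p) / p^2)
}

#' Analytic d' between two song models for a repeat-eligible element
#'
#' Closed-form d' of per-bout repetition counts implied by the shifted
#' geometric repeat law (mean `base + (1-p)/p`, variance `(1-p)/p^2`), with
#' one run per bout. Positive when the comparison model repeats more than
#' the baseline model.
#'
#' @param model_b Baseline [song_model()].
#' @param model_i Comparison [song_model()].
#' @param element Repeat-eligible element (present in both models).
#' @return Analytic d' value.
#' @examples
#' b <- song_model(p_intro = 0.9)
#' i <- apply_effect(b, song_effect(element = "i", p_rep = 0.5))
#' expected_repetition_dprime(b, i, "i")  # ~0.863
#' @export
expected_repetition_dprime <- function(model_b, model_i, element) {
  mb <- repeat_moments(model_b, element)
  mi <- repeat_moments(model_i, element)
  denom2 <- mi$var + mb$var
  if (denom2 == 0) {
    if (mi$mean == mb$mean) return(0)
    stop("degenerate repeat variances with unequal means", call. = FALSE)
  }
  sqrt(2) * (mi$mean - mb$mean) / sqrt(denom2)
}

#' Calibrate a repeat-inflation effect to a target analytic d'
#'
#' Finds a shifted-geometric repeat law `(base, p)` for `element` whose
#' analytic d' against the current model equals `target_dprime`, using the
#' smallest deterministic floor `base` for which a geometric parameter root
#' exists.
#'
#' @param model Baseline [song_model()].
#' @param element Repeat-eligible element of `model`.
#' @param target_dprime Target analytic d' (>= 0).
#' @return A [song_effect()] carrying the calibrated repeat law.
#' @export
calibrate_repeat_effect <- function(model, element, target_dprime) {
  stopifnot(target_dprime >= 0)
  if (target_dprime == 0) {
    spec <- model$repeats[[paste(as.character(element), collapse = " ")]]
    return(song_effect(element = element, p_rep = spec$p,
                       repeat_base = spec$base))
  }
  for (base in 0:50) {
    f <- function(p) {
      eff <- song_effect(element = element, p_rep = p, repeat_base = base)
      expected_repetition_dprime(model, apply_effect(model, eff), element) -
        target_dprime
    }
    lo <- 1e-6
    hi <- 1 - 1e-9
    flo <- f(lo)
    fhi <- f(hi)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0) {
      p <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
      return(song_effect(element = element, p_rep = p, repeat_base = base))
    }
  }
  stop("no repeat law found for the requested d'", call. = FALSE)
}

#' Generate a synthetic annotated recording
#'
#' Draws `n_bouts` song bouts from a [song_model()] and assembles them into a
#' single annotated recording with onset/offset times and per-rendition
#' pitch. Re-segmenting the output with the default
#' [segmentation_config()] recovers exactly `n_bouts` bouts; all randomness
#' flows from `seed`, so a fixed seed reproduces the log byte for byte.
#'
#' @param model A [song_model()].
#' @param n_bouts Number of bouts (>= 1).
#' @param seed Integer seed.
#' @param recording_id,timepoint,subject_id Metadata for the output
#'   recording.
#' @return A `song_recording` whose events carry a `pitch` column.
#' @export
generate_recording <- function(model, n_bouts, seed = 1,
                               recording_id = "sim", timepoint = NA_character_,
                               subject_id = NA_character_) {
  stopifnot(inherits(model, "song_model"), n_bouts >= 1)
  with_preserved_seed(seed, {
    novel_counter <- 0L
    bouts <- vector("list", n_bouts)
    for (b in seq_len(n_bouts)) {
      labels <- character(0)
      # intro run
      ispec <- model$repeats[[model$intro]]
      run <- 1L + ispec$base + stats::rgeom(1, ispec$p)
      labels <- c(labels, rep(model$intro, run))
      m <- if (length(model$motifs_per_bout) == 1) model$motifs_per_bout else
        sample(model$motifs_per_bout, 1)
      motif_reps <- Filter(function(r) {
        !identical(r$element, model$intro)
      }, model$repeats)
      for (mi in seq_len(m)) {
        inst <- character(0)
        pos <- 1L
        L <- length(model$motif)
        while (pos <= L) {
          matched <- NULL
          if (mi == 1L) {
            for (r in motif_reps) {
              k <- length(r$element)
              if (pos + k - 1L <= L &&
                  all(model$motif[pos:(pos + k - 1L)] == r$element)) {
                matched <- r
                break
              }
            }
          }
          if (!is.null(matched)) {
            k <- length(matched$element)
            run <- 1L + matched$base + stats::rgeom(1, matched$p)
            inst <- c(inst, rep(matched$element, run))
            pos <- pos + k
          } else {
            s <- model$motif[pos]
            if (stats::runif(1) >= model$omission_prob[[s]]) {
              inst <- c(inst, s)
            }
            pos <- pos + 1L
          }
        }
        if (model$insertion_prob > 0 &&
            stats::runif(1) < model$insertion_prob && length(inst) >= 2) {
          novel_counter <- novel_counter + 1L
          slot <- sample(length(inst) - 1L, 1)
          lab <- paste0(model$novel_prefix, novel_counter)
          inst <- append(inst, lab, after = slot)
        }
        labels <- c(labels, inst)
      }
      bouts[[b]] <- labels
    }
    # timing + pitch
    rows <- list()
    t <- 0
    for (b in seq_len(n_bouts)) {
      labels <- bouts[[b]]
      n <- length(labels)
      if (n == 0) labels <- model$intro  # degenerate safeguard
      durs <- pmax(0.02, stats::rnorm(length(labels),
                                      model$syllable_dur[["mean"]],
                                      model$syllable_dur[["sd"]]))
      gaps <- stats::runif(length(labels) - 1, model$gap_within[1],
                           model$gap_within[2])
      onsets <- t + c(0, cumsum(durs[-length(durs)] + gaps))
      offsets <- onsets + durs
      mu <- vapply(labels, function(l) {
        if (l %in% names(model$pitch_mean)) model$pitch_mean[[l]] else 700
      }, numeric(1))
      pitch <- stats::rnorm(length(labels), mu, model$pitch_cv * mu)
      rows[[b]] <- data.frame(label = labels, onset = onsets,
                              offset = offsets, pitch = pitch,
                              stringsAsFactors = FALSE)
      t <- offsets[length(offsets)] +
        stats::runif(1, model$gap_between[1], model$gap_between[2])
    }
    recording(do.call(rbind, rows), recording_id = recording_id,
              timepoint = timepoint, subject_id = subject_id)
  })
}
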