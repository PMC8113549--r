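#' d' change statistic between two samples
#'
#' The standardized change statistic used throughout the behavioral
#' analyses:
#' \deqn{d' = \sqrt{2}\,(\bar x - \bar y) / \sqrt{s_x^2 + s_y^2}}
#' with sample variances (n - 1 denominator). When the two variances are
#' equal it reads as the change in means in units of SD. Positive values mean
#' the first sample's mean exceeds the second's.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return Signed d' value.
#' @details If both variances are zero the statistic is 0 when the means are
#'   equal and an error otherwise (the change is infinite in SD units).
#' @examples
#' dprime_stat(c(2, 4), c(0, 2))  # sqrt(2)
#' @export
dprime_stat <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 observations per sample", call. = FALSE)
  }
  denom2 <- stats::var(x) + stats::var(y)
  num <- mean(x) - mean(y)
  if (denom2 == 0) {
    if (num == 0) return(0)
    stop("degenerate variances: both samples constant with unequal means",
         call. = FALSE)
  }
  sqrt(2) * num / sqrt(denom2)
}

#' d' between two repetition series
#'
#' Scores the change in per-bout repetition counts of a vocal element between
#' a timepoint and the (baseline) reference, in SD units.
#'
#' @param series_i [repetition_series()] for the timepoint of interest.
#' @param series_b [repetition_series()] for the reference (last baseline
#'   day).
#' @return An object of class `dprime_result` with fields `value`, `day_i`,
#'   `day_b`, `mean_i`, `mean_b`, `var_i`, `var_b`.
#' @export
dprime <- function(series_i, series_b) {
  stopifnot(inherits(series_i, "repetition_series"),
            inherits(series_b, "repetition_series"))
  value <- dprime_stat(series_i$counts, series_b$counts)
  structure(
    list(value = value,
         day_i = series_i$day, day_b = series_b$day,
         mean_i = series_i$mean, mean_b = series_b$mean,
         var_i = series_i$variance, var_b = series_b$variance),
    class = "dprime_result"
  )
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("d' = %.4f  (%s: mean %.3f, var %.3f vs %s: mean %.3f, var %.3f)\n",
              x$value, x$day_i, x$mean_i, x$var_i, x$day_b, x$mean_b,
              x$var_b))
  invisible(x)
}

#' Absolute pitch-shift d' between two days of renditions
#'
#' Applies the d' formula to per-rendition pitch samples and returns the
#' absolute value, together with a flag marking whether the shift exceeds the
#' learning criterion (|d'| > 0.75 by default, the threshold used to call a
#' significant pitch change in the optogenetic pitch-shift experiments).
#'
#' @param features_i,features_b Numeric vectors of per-rendition pitch
#'   (Hz) on the comparison day and the baseline day.
#' @param learning_criterion |d'| threshold for the `significant` flag.
#' @return List with `abs_dprime`, `dprime` (signed), `significant`.
#' @export
pitch_shift_dprime <- function(features_i, features_b,
                               learning_criterion = 0.75) {
  d <- dprime_stat(features_i, features_b)
  list(abs_dprime = abs(d),
       dprime = d,
       significant = abs(d) > learning_criterion)
}

#' Coefficient of variation, in percent
#'
#' `CV = 100 * sd / |mean|` with the sample standard deviation; used to
#' quantify rendition-to-rendition variability of acoustic features (pitch,
#' Wiener entropy).
#'
#' @param values Numeric vector of at least 2 values with non-zero mean.
#' @return CV as a percentage.
#' @examples
#' coefficient_of_variation(c(90, 110))  # ~14.14
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  100 * stats::sd(values) / abs(m)
}
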