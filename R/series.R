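#' Build a uniformly sampled series
#'
#' A sampled series is an ordinary tibble with columns `time_s` and `value`
#' plus `rate_hz`/`start_s` attributes, so it pipes through dplyr verbs
#' unharmed. `time_s` marks the *start* of each sampling bin; the bin centre
#' is `time_s + 1/(2 * rate_hz)`.
#'
#' @param value Numeric vector of samples.
#' @param rate_hz Sampling rate in Hz (samples per second), > 0.
#' @param start_s Time of the first bin start, seconds from recording onset.
#' @return A tibble with columns `time_s`, `value`.
#' @examples
#' sampled_series(sin(seq(0, 2 * pi, length.out = 50)), rate_hz = 10)
#' @export
sampled_series <- function(value, rate_hz, start_s = 0) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    abort_invalid("`rate_hz` must be a single positive number.")
  }
  value <- as.numeric(value)
  if (anyNA(value) || !all(is.finite(value))) {
    abort_invalid("series values must be finite.")
  }
  out <- tibble(
    time_s = start_s + (seq_along(value) - 1) / rate_hz,
    value = value
  )
  attr(out, "rate_hz") <- rate_hz
  attr(out, "start_s") <- start_s
  out
}

#' Sampling rate of a series
#'
#' Reads the `rate_hz` attribute if present, otherwise infers the rate from
#' the median spacing of `time_s`.
#'
#' @param series A tibble with a `time_s` column.
#' @return Rate in Hz.
#' @export
series_rate <- function(series) {
  r <- attr(series, "rate_hz")
  if (!is.null(r)) return(r)
  dt <- stats::median(diff(series$time_s))
  if (!is.finite(dt) || dt <= 0) abort_invalid("cannot infer sampling rate.")
  1 / dt
}

series_start <- function(series) {
  s <- attr(series, "start_s")
  if (!is.null(s)) return(s)
  series$time_s[1]
}

#' Resample a series to a coarser rate by non-overlapping bin means
#'
#' Samples are grouped into consecutive bins of width `1/target_rate_hz`
#' (anchored at the series start) and averaged; a trailing partial bin is
#' kept. Used to align modalities recorded at different rates before
#' correlating them.
#'
#' @param series A sampled series tibble.
#' @param target_rate_hz Target rate, must not exceed the series rate.
#' @return A sampled series at (approximately) the target rate.
#' @export
resample_series <- function(series, target_rate_hz) {
  rate <- series_rate(series)
  if (target_rate_hz > rate + 1e-9) {
    abort_invalid("`target_rate_hz` must be <= the series rate (downsampling only).")
  }
  if (abs(target_rate_hz - rate) < 1e-9) return(series)
  start <- series_start(series)
  bin <- floor((series$time_s - start) * target_rate_hz + 1e-9)
  value <- as.numeric(tapply(series$value, bin, mean))
  sampled_series(value, rate_hz = target_rate_hz, start_s = start)
}

#' Define an analysis window
#'
#' Windows are half-open intervals `[onset_s, offset_s)` in seconds from
#' recording onset, e.g. the low-anger and high-anger periods of a film.
#'
#' @param label Window label, e.g. `"low-anger"` or `"high-anger"`.
#' @param onset_s,offset_s Window bounds in seconds, `offset_s > onset_s`.
#' @return A `window_spec` object (a named list).
#' @export
window_spec <- function(label, onset_s, offset_s) {
  if (!is.character(label) || length(label) != 1L) {
    abort_invalid("`label` must be a single string.")
  }
  if (!is.finite(onset_s) || !is.finite(offset_s) || offset_s <= onset_s) {
    abort_invalid("need finite `offset_s` > `onset_s`.")
  }
  structure(
    list(label = label, onset_s = onset_s, offset_s = offset_s),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window '%s': [%g, %g) s>\n", x$label, x$onset_s, x$offset_s))
  invisible(x)
}

#' Mean of a series over a window
#'
#' Averages the samples whose bin centres fall inside `[onset_s, offset_s)`.
#' Errors if the window captures no sample.
#'
#' @param series A sampled series tibble.
#' @param window A [window_spec()].
#' @return A single number.
#' @examples
#' s <- sampled_series(0:8, rate_hz = 1)
#' window_mean(s, window_spec("mid", 1.6, 4.6)) # samples 2,3,4 -> 3
#' @export
window_mean <- function(series, window) {
  stopifnot(inherits(window, "window_spec"))
  rate <- series_rate(series)
  centre <- series$time_s + 1 / (2 * rate)
  keep <- centre >= window$onset_s & centre < window$offset_s
  if (!any(keep)) {
    abort_invalid(sprintf(
      "window '%s' [%g, %g) contains no sample of a series covering [%g, %g).",
      window$label, window$onset_s, window$offset_s,
      min(series$time_s), max(series$time_s) + 1 / rate
    ))
  }
  mean(series$value[keep])
}

# Canonical double-gamma hemodynamic response function, sampled at `dt_s`
# over `duration_s`, unit-sum normalized.  SPM-style shapes (6, 16), scale 1,
# undershoot ratio 1/6; peak ~5-6 s after a brief neural event.
hrf_kernel <- function(dt_s, duration_s = 32) {
  t <- seq(0, duration_s, by = dt_s)
  h <- dgamma(t, shape = 6, scale = 1) - dgamma(t, shape = 16, scale = 1) / 6
  h / sum(h)
}

# Causal convolution of a sampled signal with a kernel, truncated to the
# input length (edge transient at the start is kept, not trimmed).
convolve_causal <- function(x, kernel) {
  out <- stats::convolve(x, rev(kernel), type = "open")
  out[seq_along(x)]
}

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "angerefp_invalid_argument")
}
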