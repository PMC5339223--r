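#' Group-mean continuous rating trace
#'
#' Pointwise mean across subjects. Traces of unequal length are trimmed to
#' the shortest with a warning.
#'
#' @param traces List of sampled series (one per subject) sharing a rate,
#'   or a long tibble with columns `subject`, `time_s`, `value`.
#' @return A sampled series tibble.
#' @export
group_mean_trace <- function(traces) {
  if (is.data.frame(traces)) {
    stopifnot(all(c("subject", "time_s", "value") %in% names(traces)))
    traces <- lapply(split(traces, traces$subject), function(d) {
      d <- d[order(d$time_s), ]
      s <- sampled_series(d$value, rate_hz = 1 / stats::median(diff(d$time_s)),
                          start_s = d$time_s[1])
      s
    })
  }
  if (length(traces) == 0) abort_invalid("no traces supplied.")
  lens <- vapply(traces, nrow, integer(1))
  if (length(unique(lens)) > 1) {
    warn(sprintf("trimming traces to the shortest length (%d samples).",
                 min(lens)))
  }
  n <- min(lens)
  rate <- series_rate(traces[[1]])
  vals <- rowMeans(vapply(traces, function(s) s$value[seq_len(n)],
                          numeric(n)))
  sampled_series(vals, rate_hz = rate, start_s = series_start(traces[[1]]))
}

#' Locate the low- and high-anger windows
#'
#' The high-anger window is the `width_s`-second window maximizing the
#' sliding mean of the group rating trace, scanned on a 1-s onset grid
#' (earliest onset wins ties). Following the most literal reading of the
#' construction, the low-anger window is fixed to the first `width_s`
#' seconds of the recording; `low_scan = TRUE` instead scans for the
#' minimizing window whose onset lies within `low_range`.
#'
#' @param mean_trace Group-mean sampled series (see [group_mean_trace()]).
#' @param width_s Window width in seconds (default 100).
#' @param step_s Onset grid step for the scan.
#' @param low_scan If `TRUE`, pick the minimizing window within
#'   `low_range` instead of the fixed initial window.
#' @param low_range Onset range (s) searched when `low_scan = TRUE`.
#' @return A list with `low` and `high` [window_spec()] objects.
#' @export
find_windows <- function(mean_trace, width_s = 100, step_s = 1,
                         low_scan = FALSE, low_range = c(0, width_s)) {
  rate <- series_rate(mean_trace)
  start <- series_start(mean_trace)
  duration <- nrow(mean_trace) / rate
  if (duration < width_s) abort_invalid("trace shorter than the window width.")
  onsets <- seq(start, start + duration - width_s, by = step_s)
  means <- vapply(onsets, function(o) {
    window_mean(mean_trace, window_spec("scan", o, o + width_s))
  }, numeric(1))
  hi_on <- onsets[which.max(means)] # which.max: earliest onset on ties
  high <- window_spec("high-anger", hi_on, hi_on + width_s)
  low <- if (low_scan) {
    ok <- onsets >= low_range[1] & onsets + width_s <= low_range[2] + width_s &
      onsets <= low_range[2]
    lo_on <- onsets[ok][which.min(means[ok])]
    window_spec("low-anger", lo_on, lo_on + width_s)
  } else {
    window_spec("low-anger", start, start + width_s)
  }
  list(low = low, high = high)
}

#' Median intensity per emotion label
#'
#' Per-label medians of a subject x label grid of 1..7 intensity ratings,
#' sorted by descending median (then label).
#'
#' @param label_ratings Matrix or data frame, one column per emotion
#'   label, values in 1..7.
#' @return A tibble (`label`, `median`) sorted descending.
#' @export
summarize_labels <- function(label_ratings) {
  m <- as.matrix(label_ratings)
  if (any(m < 1 | m > 7)) abort_invalid("ratings must lie in 1..7.")
  med <- apply(m, 2, median)
  out <- tibble(label = colnames(m) %||% paste0("label", seq_len(ncol(m))),
                median = unname(med))
  arrange(out, desc(.data$median), .data$label)
}
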