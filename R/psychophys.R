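#' Heart-rate series from R-peak times
#'
#' Applies the previous-interval rule: between peaks k and k+1 the
#' instantaneous rate is `60 / (t_k - t_{k-1})` bpm (the duration of the
#' interval just completed, converted to beats per minute). The piecewise
#' constant signal is then resampled into 1-s bins by the time-weighted
#' mean. Time before the second peak has no previous interval; those bins
#' are back-filled with the first defined value (set
#' `backfill = FALSE` to leave them `NA` and have them dropped).
#'
#' @param rpeaks Strictly increasing R-peak times, seconds.
#' @param duration_s Recording duration; bins cover `[0, ceiling(duration))`.
#' @param bin_s Bin width in seconds.
#' @param backfill Back-fill the leading bins (default) or drop them.
#' @return A sampled series tibble (`time_s`, `value` in bpm) with a
#'   `n_peaks` attribute recording the provenance count.
#' @examples
#' rr_to_hr(0:10, duration_s = 10) # 60 bpm everywhere
#' @export
rr_to_hr <- function(rpeaks, duration_s = NULL, bin_s = 1, backfill = TRUE) {
  if (length(rpeaks) < 2) abort_invalid("need at least 2 R-peaks.")
  if (any(diff(rpeaks) <= 0)) abort_invalid("R-peaks must be strictly increasing.")
  duration_s <- duration_s %||% max(rpeaks)
  n_bins <- ceiling(duration_s / bin_s)
  rr <- diff(rpeaks)
  bpm <- 60 / rr
  # segment j: [rpeaks[j+1], rpeaks[j+2]) carries bpm[j] (previous interval);
  # the tail after the last peak carries the last interval's value.
  seg_start <- rpeaks[-1]
  seg_end <- c(rpeaks[-(1:2)], Inf)
  first_defined <- bpm[1]
  value <- vapply(seq_len(n_bins), function(b) {
    lo <- (b - 1) * bin_s; hi <- b * bin_s
    w_def <- pmax(pmin(seg_end, hi) - pmax(seg_start, lo), 0)
    covered <- sum(w_def)
    undefined <- (hi - lo) - covered
    if (covered == 0 && !backfill) return(NA_real_)
    num <- sum(w_def * bpm) + if (backfill) undefined * first_defined else 0
    den <- covered + if (backfill) undefined else 0
    num / den
  }, numeric(1))
  out <- sampled_series(value[!is.na(value)], rate_hz = 1 / bin_s,
                        start_s = if (backfill) 0 else
                          (which(!is.na(value))[1] - 1) * bin_s)
  attr(out, "n_peaks") <- length(rpeaks)
  out
}

#' Rank correlation between two modalities, one subject
#'
#' Both series are resampled to the coarser of the two rates by
#' non-overlapping means, aligned on overlapping bins, and the Spearman
#' correlation is computed. Returns `NA` (with a message) if either
#' aligned series is constant.
#'
#' @param series_a,series_b Sampled series tibbles.
#' @param min_samples Minimum number of aligned samples required.
#' @return Spearman rho (scalar, possibly `NA`).
#' @export
series_coupling <- function(series_a, series_b, min_samples = 5) {
  target <- min(series_rate(series_a), series_rate(series_b))
  a <- resample_series(series_a, target)
  b <- resample_series(series_b, target)
  n <- min(nrow(a), nrow(b))
  if (n < min_samples) abort_invalid("fewer aligned samples than `min_samples`.")
  av <- a$value[seq_len(n)]; bv <- b$value[seq_len(n)]
  if (sd(av) < 1e-12 || sd(bv) < 1e-12) return(NA_real_)
  cor(av, bv, method = "spearman")
}

#' Group-level coupling between two modalities
#'
#' Computes the per-subject Spearman correlation with [series_coupling()]
#' and performs a two-sided one-sample t-test on the raw coefficients (not
#' Fisher-transformed, matching how such couplings are conventionally
#' reported). Subjects with an undefined correlation (constant series) are
#' dropped and counted.
#'
#' @param series_a,series_b Lists of sampled series, one per subject, in
#'   matching order.
#' @return A `coupling_result`: per-subject rho, group mean, t, df, p.
#' @export
coupling_stats <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b))
  rho <- vapply(seq_along(series_a), function(i) {
    series_coupling(series_a[[i]], series_b[[i]])
  }, numeric(1))
  n_dropped <- sum(is.na(rho))
  if (n_dropped > 0) {
    inform(sprintf("dropping %d subject(s) with undefined correlation.",
                   n_dropped))
  }
  ok <- rho[!is.na(rho)]
  if (length(ok) < 2) abort_invalid("need >= 2 subjects with defined rho.")
  tt <- t.test(ok)
  structure(
    list(rho = rho, mean_rho = mean(ok),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, n = length(ok), n_dropped = n_dropped),
    class = "coupling_result"
  )
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf(
    "<coupling: mean Spearman r = %.3f, t(%d) = %.2f, p = %.3g, n = %d>\n",
    x$mean_rho, x$df, x$t, x$p, x$n))
  invisible(x)
}

#' @describeIn coupling_stats Per-subject tidy table.
#' @param x A `coupling_result`.
#' @param ... Unused.
#' @export
tidy.coupling_result <- function(x, ...) {
  tibble(subject = seq_along(x$rho), rho = x$rho)
}

#' @describeIn coupling_stats One-row group summary.
#' @export
glance.coupling_result <- function(x, ...) {
  tibble(mean_rho = x$mean_rho, t = x$t, df = x$df, p = x$p,
         n = x$n, n_dropped = x$n_dropped)
}

#' Paired comparison of low- vs high-anger window values
#'
#' Two-sided paired t-test (df = n - 1). A zero-variance difference vector
#' triggers the degenerate branch: `t` and `p` are returned `NA` with a
#' warning rather than a spurious infinity.
#'
#' @param values_low,values_high Per-subject scalars, equal length.
#' @return A one-row tibble: `mean_diff`, `t`, `df`, `p`, `n`.
#' @export
paired_window_test <- function(values_low, values_high) {
  if (length(values_low) != length(values_high)) {
    abort_invalid("paired vectors must have equal length.")
  }
  keep <- is.finite(values_low) & is.finite(values_high)
  lo <- values_low[keep]; hi <- values_high[keep]
  n <- length(lo)
  if (n < 3) abort_invalid("need at least 3 complete pairs.")
  d <- hi - lo
  if (sd(d) < 1e-12) {
    warn("zero-variance differences: t undefined.")
    return(tibble(mean_diff = mean(d), t = NA_real_, df = n - 1,
                  p = NA_real_, n = n))
  }
  tt <- t.test(hi, lo, paired = TRUE)
  tibble(mean_diff = mean(d), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, n = n)
}
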