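#' EEG time-frequency tensor
#'
#' A channel x band x frame array of (log) band-power features with channel
#' labels, band edges and the frame length attached. This is the object the
#' fingerprint model consumes; [eeg_spectrogram()] builds it from raw
#' traces and [generate_eeg()] simulates it directly.
#'
#' @param values 3-axis numeric array (channel, band, frame). The first two
#'   axes may carry dimnames; channel labels default to `ch01, ch02, ...`.
#' @param band_edges_hz Strictly increasing band edges, length `n_bands + 1`.
#' @param frame_s Frame length in seconds.
#' @param start_s Time of the first frame start.
#' @return An `eeg_tf` object.
#' @export
eeg_tf <- function(values, band_edges_hz, frame_s, start_s = 0) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (any(!is.finite(values))) abort_invalid("tensor values must be finite.")
  if (any(diff(band_edges_hz) <= 0)) {
    abort_invalid("`band_edges_hz` must be strictly increasing.")
  }
  if (length(band_edges_hz) != dim(values)[2] + 1) {
    abort_invalid("`band_edges_hz` must have n_bands + 1 entries.")
  }
  dn <- dimnames(values) %||% vector("list", 3)
  if (is.null(dn[[1]])) dn[[1]] <- sprintf("ch%02d", seq_len(dim(values)[1]))
  if (is.null(dn[[2]])) dn[[2]] <- band_names(band_edges_hz)
  dn[[3]] <- NULL
  dimnames(values) <- dn
  structure(values, band_edges_hz = band_edges_hz, frame_s = frame_s,
            start_s = start_s, class = "eeg_tf")
}

#' @export
print.eeg_tf <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<eeg_tf: %d channels x %d bands x %d frames of %g s (%.0f s total)>\n",
    d[1], d[2], d[3], attr(x, "frame_s"), d[3] * attr(x, "frame_s")))
  cat("channels:", paste(dimnames(x)[[1]], collapse = ", "), "\n")
  invisible(x)
}

tf_channels <- function(tf) dimnames(tf)[[1]]
tf_bands <- function(tf) dimnames(tf)[[2]]
tf_frame_s <- function(tf) attr(tf, "frame_s")
tf_start_s <- function(tf) attr(tf, "start_s")

#' Tidy a time-frequency tensor
#'
#' @param x An `eeg_tf` tensor.
#' @param ... Unused.
#' @return A long tibble: `channel`, `band`, `frame`, `time_s`, `value`.
#' @export
tidy.eeg_tf <- function(x, ...) {
  d <- dim(x)
  tibble(
    channel = rep(dimnames(x)[[1]], times = d[2] * d[3]),
    band = rep(rep(dimnames(x)[[2]], each = d[1]), times = d[3]),
    frame = rep(seq_len(d[3]), each = d[1] * d[2]),
    time_s = tf_start_s(x) + (rep(seq_len(d[3]), each = d[1] * d[2]) - 1) *
      tf_frame_s(x),
    value = as.vector(unclass(x))
  )
}

#' Short-time band-power features from raw EEG
#'
#' Cuts each channel into non-overlapping frames, computes the periodogram
#' of each frame (Hann-tapered FFT), averages power within each frequency
#' band, log-transforms (with a small guard against zero power) and
#' z-scores every (channel, band) feature over frames.
#'
#' @param raw Channel x sample numeric matrix of raw traces (rownames are
#'   channel labels).
#' @param rate_hz Sampling rate of the raw traces; must be at least twice
#'   the top band edge.
#' @param frame_s Frame length in seconds.
#' @param band_edges_hz Band edges in Hz.
#' @return An `eeg_tf` tensor.
#' @export
eeg_spectrogram <- function(raw, rate_hz, frame_s = 3,
                            band_edges_hz = default_band_edges()) {
  stopifnot(is.matrix(raw))
  if (rate_hz < 2 * max(band_edges_hz)) {
    abort_invalid("`rate_hz` must be at least twice the top band edge.")
  }
  spf <- round(frame_s * rate_hz)
  if (spf > ncol(raw)) abort_invalid("frame longer than the recording.")
  nframes <- ncol(raw) %/% spf
  nb <- length(band_edges_hz) - 1
  freqs <- (seq_len(spf %/% 2 + 1) - 1) * rate_hz / spf
  band_of <- cut(freqs, band_edges_hz, right = FALSE, labels = FALSE)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, spf - 1) / (spf - 1))
  values <- array(0, dim = c(nrow(raw), nb, nframes))
  for (ch in seq_len(nrow(raw))) {
    for (fr in seq_len(nframes)) {
      seg <- raw[ch, ((fr - 1) * spf + 1):(fr * spf)] * taper
      pw <- Mod(fft(seg))[seq_along(freqs)]^2
      for (b in seq_len(nb)) {
        values[ch, b, fr] <- mean(pw[which(band_of == b)])
      }
    }
  }
  values <- log(values + 1e-12)
  # z-score each (channel, band) over frames; constant features stay at 0
  for (ch in seq_len(dim(values)[1])) {
    for (b in seq_len(nb)) {
      v <- values[ch, b, ]
      s <- sd(v)
      values[ch, b, ] <- if (is.finite(s) && s > 0) (v - mean(v)) / s else 0
    }
  }
  dimnames(values) <- list(rownames(raw) %||%
                             sprintf("ch%02d", seq_len(nrow(raw))),
                           band_names(band_edges_hz), NULL)
  eeg_tf(values, band_edges_hz = band_edges_hz, frame_s = spf / rate_hz)
}

#' Delay-embed one channel of a time-frequency tensor
#'
#' Builds the frame x (band * delay) design matrix whose column `(f, d)`
#' holds feature `(f, t - d)`; the EEG-to-BOLD hemodynamic lag is captured
#' by these delayed copies. Column order is bands-major: all delays of band
#' 1, then band 2, ... Initial frames with missing lags are dropped
#' (default) or left-padded with the earliest frame, which is what
#' [predict_efp()] uses so that the prediction keeps the full frame count.
#'
#' @param tf An `eeg_tf` tensor.
#' @param channel Channel label to embed.
#' @param delays_frames Number of delays (>= 1); delay 0 is the current
#'   frame.
#' @param pad If `TRUE`, keep all frames by padding missing lags.
#' @return A numeric matrix with an attribute `frames` giving the frame
#'   indices of its rows.
#' @export
embed_delays <- function(tf, channel, delays_frames = 6, pad = FALSE) {
  stopifnot(inherits(tf, "eeg_tf"))
  if (delays_frames < 1) abort_invalid("`delays_frames` must be >= 1.")
  if (!channel %in% tf_channels(tf)) {
    abort_invalid(sprintf("channel '%s' not in tensor (available: %s).",
                          channel, paste(tf_channels(tf), collapse = ", ")))
  }
  nf <- dim(tf)[3]
  if (delays_frames >= nf && !pad) {
    abort_invalid("`delays_frames` must be smaller than the frame count.")
  }
  feat <- unclass(tf)[channel, , , drop = TRUE] # band x frame
  if (is.null(dim(feat))) feat <- matrix(feat, nrow = 1)
  bands <- tf_bands(tf)
  frames <- if (pad) seq_len(nf) else delays_frames:nf
  cols <- list()
  for (b in seq_along(bands)) {
    for (d in seq_len(delays_frames) - 1) {
      idx <- pmax(frames - d, 1)
      cols[[paste0(bands[b], "_lag", d)]] <- feat[b, idx]
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "frames") <- frames
  attr(X, "bands") <- bands
  attr(X, "delays_frames") <- delays_frames
  X
}
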