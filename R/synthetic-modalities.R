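#' Default EEG frequency bands
#'
#' Band edges in Hz for the five classical bands delta (1-4), theta (4-8),
#' alpha (8-12), beta (12-30) and gamma (30-40).
#'
#' @return Numeric vector of band edges.
#' @export
default_band_edges <- function() c(1, 4, 8, 12, 30, 40)

band_names <- function(band_edges_hz) {
  n <- length(band_edges_hz) - 1
  classical <- c("delta", "theta", "alpha", "beta", "gamma")
  if (n == 5) classical else paste0("band", seq_len(n))
}

band_centers <- function(band_edges_hz) {
  (head(band_edges_hz, -1) + tail(band_edges_hz, -1)) / 2
}

#' Ground-truth EEG coupling specification
#'
#' Defines how the latent anger trace drives EEG band power, BOLD, heart
#' rate and ratings in the synthetic cohort, and serves as the ground truth
#' for parameter-recovery tests. The default weight grid is a separable
#' channel-gain x spectral-profile x delay-profile product: a right
#' frontotemporal channel (F8) carries the dominant coupling, alpha power is
#' negatively and gamma positively coupled (the classical band-power/BOLD
#' sign pattern), and the coupling decays exponentially over ~15 s of lag
#' (time constant 7.5 s), mirroring the sluggish hemodynamic integration
#' the fingerprint emulates.
#'
#' @param channel_labels EEG channel names.
#' @param band_edges_hz Band edges in Hz.
#' @param n_delays Number of frame delays carried by the weight grid.
#' @param frame_s Frame length in seconds used for the delay grid.
#' @param eeg_weights Optional channel x band x delay array overriding the
#'   default. Exactly one channel must hold the maximal total absolute
#'   weight (ties would make electrode-selection recovery ill-posed).
#' @param target_electrode Channel with the dominant coupling.
#' @param bold_snr,eeg_snr Signal-to-noise variance ratios (> 0).
#' @param hr_gain Heart-rate gain in bpm per latent unit.
#' @param rating_lag_s Lag of the retrospective rating behind the latent.
#' @param rating_noise_sd Rating noise, in rating levels.
#' @return A `coupling_spec` object.
#' @export
coupling_spec <- function(channel_labels = c("F3", "F4", "F7", "F8", "Fz", "Pz"),
                          band_edges_hz = default_band_edges(),
                          n_delays = 6, frame_s = 3,
                          eeg_weights = NULL,
                          target_electrode = "F8",
                          bold_snr = 1, eeg_snr = 1,
                          hr_gain = 8, rating_lag_s = 2,
                          rating_noise_sd = 1) {
  if (bold_snr <= 0 || eeg_snr <= 0) abort_invalid("SNRs must be > 0.")
  nb <- length(band_edges_hz) - 1
  if (is.null(eeg_weights)) {
    gains <- setNames(rep(0, length(channel_labels)), channel_labels)
    gains[intersect(c("F3", "F4", "F7", "Fz"), channel_labels)] <-
      c(F3 = 0.30, F4 = 0.55, F7 = 0.45, Fz = 0.20)[
        intersect(c("F3", "F4", "F7", "Fz"), channel_labels)]
    if (!target_electrode %in% channel_labels) {
      abort_invalid("`target_electrode` must be one of `channel_labels`.")
    }
    gains[target_electrode] <- 1
    spectral <- c(0.3, 0.5, -1.0, -0.4, 0.6)
    if (nb != 5) spectral <- rep_len(c(1, -1), nb)
    # coupling decays smoothly over ~15 s of lag; the sluggish hemodynamic
    # integration the fingerprint emulates makes a broad profile, not a
    # sharp peak, the recoverable ground truth
    lag_s <- (seq_len(n_delays) - 1) * frame_s
    delayprof <- exp(-lag_s / 7.5)
    eeg_weights <- outer(gains, outer(spectral, delayprof))
    dimnames(eeg_weights) <- list(channel_labels, band_names(band_edges_hz),
                                  paste0("lag", seq_len(n_delays) - 1))
  }
  stopifnot(length(dim(eeg_weights)) == 3,
            dim(eeg_weights)[1] == length(channel_labels),
            dim(eeg_weights)[2] == nb)
  totals <- apply(abs(eeg_weights), 1, sum)
  top <- which(totals == max(totals))
  if (length(top) != 1) {
    abort_invalid("exactly one channel must hold the maximal total absolute weight.")
  }
  if (channel_labels[top] != target_electrode) {
    abort_invalid("`target_electrode` must hold the maximal total absolute weight.")
  }
  structure(
    list(
      channel_labels = channel_labels, band_edges_hz = band_edges_hz,
      frame_s = frame_s, eeg_weights = eeg_weights,
      target_electrode = target_electrode,
      bold_snr = bold_snr, eeg_snr = eeg_snr, hr_gain = hr_gain,
      rating_lag_s = rating_lag_s, rating_noise_sd = rating_noise_sd
    ),
    class = "coupling_spec"
  )
}

#' Simulate ROI BOLD voxels from the latent trace
#'
#' Coupled voxels are the latent trace convolved with the canonical
#' double-gamma hemodynamic response, resampled to the TR grid by
#' non-overlapping means, plus independent Gaussian noise at the stated
#' signal-to-noise variance ratio. Null voxels are pure noise of matched
#' scale. The ROI mean over coupled voxels is returned alongside.
#'
#' @param latent Latent sampled series from [generate_latent()].
#' @param n_coupled,n_null Number of coupled / pure-noise voxels.
#' @param tr_s Repetition time in seconds (volume sampling interval).
#' @param snr Signal variance / noise variance; `Inf` for noiseless voxels.
#' @param seed Integer seed.
#' @return A `bold_sim` list: `voxels` (voxel x frame matrix), `roi` and
#'   `clean_roi` (sampled series at `1/tr_s` Hz), `tr_s`.
#' @export
generate_bold <- function(latent, n_coupled = 30, n_null = 30, tr_s = 3,
                          snr = 1, seed = 1) {
  if (tr_s <= 0) abort_invalid("`tr_s` must be positive.")
  rate <- series_rate(latent)
  duration <- nrow(latent) / rate
  if (duration < tr_s) abort_invalid("latent series is shorter than one TR.")
  clean10 <- convolve_causal(latent$value, hrf_kernel(1 / rate))
  clean <- resample_series(
    sampled_series(clean10, rate_hz = rate, start_s = series_start(latent)),
    target_rate_hz = 1 / tr_s
  )
  nf <- nrow(clean)
  scale_sd <- sd(clean$value)
  if (!is.finite(scale_sd) || scale_sd == 0) scale_sd <- 1
  noise_sd <- if (is.infinite(snr)) 0 else scale_sd / sqrt(snr)
  voxels <- withr::with_seed(seed, {
    coupled <- if (n_coupled > 0) {
      matrix(rep(clean$value, each = n_coupled), n_coupled, nf) +
        matrix(rnorm(n_coupled * nf, 0, noise_sd), n_coupled, nf)
    }
    nullv <- if (n_null > 0) {
      matrix(rnorm(n_null * nf, 0, scale_sd), n_null, nf)
    }
    rbind(coupled, nullv)
  })
  rn <- c(if (n_coupled > 0) sprintf("coupled_%03d", seq_len(n_coupled)),
          if (n_null > 0) sprintf("null_%03d", seq_len(n_null)))
  rownames(voxels) <- rn
  roi <- if (n_coupled > 0) {
    sampled_series(colMeans(voxels[seq_len(n_coupled), , drop = FALSE]),
                   rate_hz = 1 / tr_s, start_s = series_start(latent))
  }
  structure(
    list(voxels = voxels, roi = roi, clean_roi = clean, tr_s = tr_s,
         n_coupled = n_coupled, n_null = n_null),
    class = "bold_sim"
  )
}

# Latent trace averaged into non-overlapping frames, padded at the left edge
# by the first frame when a delayed copy runs off the start of the recording.
latent_frames <- function(latent, frame_s) {
  resample_series(latent, target_rate_hz = 1 / frame_s)$value
}

#' Simulate the EEG time-frequency tensor
#'
#' The band-power feature of channel c, band f at frame t is the
#' delay-weighted sum `sum_d w[c,f,d] * latent(t - d)` on the frame grid,
#' plus Gaussian noise with a pink (1/f power) profile across bands,
#' calibrated so that, at the target electrode, total signal variance /
#' total noise variance equals `coupling$eeg_snr`.
#'
#' @param latent Latent sampled series.
#' @param coupling A [coupling_spec()].
#' @param frame_s Frame length in seconds.
#' @param seed Integer seed.
#' @return An `eeg_tf` tensor (see [eeg_tf()]).
#' @export
generate_eeg <- function(latent, coupling = coupling_spec(), frame_s = 3,
                         seed = 1) {
  stopifnot(inherits(coupling, "coupling_spec"))
  w <- coupling$eeg_weights
  nch <- dim(w)[1]; nb <- dim(w)[2]; nd <- dim(w)[3]
  L <- latent_frames(latent, frame_s)
  nf <- length(L)
  if (nd >= nf) abort_invalid("delay depth exceeds the series length in frames.")
  # delayed copies, left-padded with the first frame value
  Ld <- vapply(seq_len(nd) - 1, function(d) {
    c(rep(L[1], d), L[seq_len(nf - d)])
  }, numeric(nf)) # frame x delay
  clean <- array(0, dim = c(nch, nb, nf))
  for (ch in seq_len(nch)) {
    for (f in seq_len(nb)) {
      clean[ch, f, ] <- Ld %*% w[ch, f, ]
    }
  }
  target <- match(coupling$target_electrode, coupling$channel_labels)
  sig_var <- mean(apply(clean[target, , , drop = FALSE], 2, var))
  if (!is.finite(sig_var) || sig_var < 1e-12) sig_var <- 1
  # pink (1/f power) noise profile: power ~ 1/f, so the SD scales as 1/sqrt(f)
  pink <- 1 / sqrt(band_centers(coupling$band_edges_hz))
  pink <- pink / sqrt(mean(pink^2))
  base_sd <- if (is.infinite(coupling$eeg_snr)) 0 else
    sqrt(sig_var / coupling$eeg_snr)
  values <- withr::with_seed(seed, {
    noise <- array(rnorm(nch * nb * nf), dim = c(nch, nb, nf)) *
      rep(base_sd * pink, each = nch)
    clean + noise
  })
  dimnames(values) <- list(coupling$channel_labels,
                           band_names(coupling$band_edges_hz), NULL)
  eeg_tf(values, band_edges_hz = coupling$band_edges_hz, frame_s = frame_s,
         start_s = series_start(latent))
}

#' Simulate R-peak event times
#'
#' Inter-beat intervals follow `60 / (base_bpm + hr_gain * latent(t))` plus
#' Gaussian jitter (heart-rate variability); peaks are strictly increasing
#' and the first peak sits at time 0.
#'
#' @param latent Latent sampled series.
#' @param base_bpm Baseline heart rate, bpm.
#' @param hr_gain Gain in bpm per latent unit (defaults to the coupling
#'   spec's value).
#' @param jitter_sd_s Jitter SD of each interval, seconds.
#' @param seed Integer seed.
#' @return Numeric vector of R-peak times in seconds.
#' @export
generate_rr <- function(latent, base_bpm = 70, hr_gain = 8,
                        jitter_sd_s = 0.02, seed = 1) {
  if (base_bpm <= 0) abort_invalid("`base_bpm` must be positive.")
  duration <- nrow(latent) / series_rate(latent)
  if (min(base_bpm + hr_gain * latent$value) <= 0) {
    abort_invalid("parameters produce a non-positive instantaneous bpm.")
  }
  withr::with_seed(seed, {
    peaks <- 0
    t <- 0
    repeat {
      bpm <- base_bpm + hr_gain * series_at(latent, t)
      rr <- 60 / bpm + rnorm(1, 0, jitter_sd_s)
      rr <- max(rr, 0.25 * 60 / bpm) # jitter never collapses an interval
      t <- t + rr
      if (t >= duration - 1e-9) break # the recording is [0, duration)
      peaks <- c(peaks, t)
    }
    peaks
  })
}

#' Simulate the continuous anger rating
#'
#' A lagged monotone (affine) transform of the latent trace plus Gaussian
#' noise, quantized to the 21-level rating grid (0..20) at 10 Hz. Without an
#' explicit `map`, the latent's central range is mapped onto levels 2..16.
#'
#' @param latent Latent sampled series.
#' @param lag_s Rating lag behind the latent, seconds (>= 0).
#' @param noise_sd Noise SD in rating levels.
#' @param map Optional `c(intercept, slope)` giving
#'   `level = intercept + slope * latent`; overrides the automatic scaling.
#' @param rate_hz Rating sample rate.
#' @param n_levels Number of rating levels (grid `0 .. n_levels - 1`).
#' @param seed Integer seed.
#' @return A sampled series tibble whose values lie on the integer grid.
#' @export
generate_rating <- function(latent, lag_s = 2, noise_sd = 1, map = NULL,
                            rate_hz = 10, n_levels = 21, seed = 1) {
  if (lag_s < 0) abort_invalid("`lag_s` must be >= 0.")
  duration <- nrow(latent) / series_rate(latent)
  t <- seq(0, duration - 1 / rate_hz, by = 1 / rate_hz)
  x <- series_at(latent, pmax(t - lag_s, 0))
  if (is.null(map)) {
    lo <- unname(quantile(x, 0.05)); hi <- unname(quantile(x, 0.95))
    if (hi - lo < 1e-12) {
      map <- c(2, 0)
    } else {
      map <- c(2 - 14 * lo / (hi - lo), 14 / (hi - lo))
    }
  }
  raw <- map[1] + map[2] * x
  level <- withr::with_seed(seed, raw + rnorm(length(raw), 0, noise_sd))
  level <- pmin(pmax(round(level), 0), n_levels - 1)
  sampled_series(level, rate_hz = rate_hz, start_s = 0)
}

#' Simulate dot-probe trials for one subject
#'
#' Reaction times have a lognormal body; congruent trials (probe at the
#' angry-face location) are shifted by `-true_bias_ms` relative to
#' incongruent trials, so a positive bias means vigilance. A small fraction
#' of fast guesses (< 150 ms) and incorrect responses is injected so that
#' the scoring exclusion rules are exercised.
#'
#' @param n_congruent,n_incongruent Angry/neutral trials with the probe at
#'   the angry / neutral face location.
#' @param n_neutral_pairs Neutral/neutral filler trials.
#' @param true_bias_ms Ground-truth attention bias in ms.
#' @param rt_params List with `meanlog`, `sdlog` (lognormal RT body, ms) and
#'   `guess_rate` (probability of a fast guess).
#' @param error_rate Probability of an incorrect response.
#' @param seed Integer seed.
#' @return A tibble of trials: `pair_type`, `probe_at_angry_location`,
#'   `rt_ms`, `correct`.
#' @export
generate_dotprobe <- function(n_congruent = 64, n_incongruent = 64,
                              n_neutral_pairs = 32, true_bias_ms = 0,
                              rt_params = list(meanlog = log(520),
                                               sdlog = 0.15,
                                               guess_rate = 0.03),
                              error_rate = 0.05, seed = 1) {
  if (n_congruent <= 0 || n_incongruent <= 0 || n_neutral_pairs <= 0) {
    abort_invalid("trial counts must be positive.")
  }
  if (error_rate < 0 || error_rate >= 1) {
    abort_invalid("`error_rate` must lie in [0, 1).")
  }
  withr::with_seed(seed, {
    n <- n_congruent + n_incongruent + n_neutral_pairs
    trials <- tibble(
      pair_type = rep(c("angry-neutral", "angry-neutral", "neutral-neutral"),
                      c(n_congruent, n_incongruent, n_neutral_pairs)),
      probe_at_angry_location = rep(c(TRUE, FALSE, NA),
                                    c(n_congruent, n_incongruent,
                                      n_neutral_pairs))
    )
    rt <- rlnorm(n, rt_params$meanlog, rt_params$sdlog)
    rt[which(trials$probe_at_angry_location)] <-
      rt[which(trials$probe_at_angry_location)] - true_bias_ms
    guess <- runif(n) < rt_params$guess_rate
    rt[guess] <- runif(sum(guess), 80, 149)
    trials$rt_ms <- rt
    trials$correct <- runif(n) >= error_rate
    trials[sample.int(n), ]
  })
}
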