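# Shared fixtures, built in code at test time.

# A short latent profile for fast tests that do not need the full film.
short_profile <- function() {
  latent_profile(duration_s = 120, bump_onset_s = 40, bump_peak_s = 55,
                 bump_offset_s = 85)
}

# A tiny tensor with known content: values[ch, band, frame].
tiny_tf <- function(values, frame_s = 3) {
  eeg_tf(values, band_edges_hz = seq_len(dim(values)[2] + 1) * 4,
         frame_s = frame_s)
}

# Deterministic per-subject synthetic pair (tensor, ROI series) from the
# default generator, for fingerprint-fit tests.
cohort_pair <- function(seed, latent, coupling, n_coupled = 10) {
  list(
    eeg = generate_eeg(latent, coupling, seed = seed),
    bold = generate_bold(latent, n_coupled = n_coupled, n_null = 0,
                         snr = coupling$bold_snr, seed = seed + 5000)
  )
}

# Hand-built fingerprint model (band x delay grid given by `grid`).
manual_model <- function(grid, cv_fit_r = 0.5, electrode = "F8",
                         intercept = 0, frame_s = 3) {
  angerefp:::new_efp_model(
    as.vector(t(grid)), intercept, 1, rownames(grid) %||%
      paste0("b", seq_len(nrow(grid))), ncol(grid), electrode, cv_fit_r,
    band_edges_hz = seq_len(nrow(grid) + 1), frame_s = frame_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trial-table builder for dot-probe fixtures.
mk_trials <- function(congruent, incongruent, neutral = numeric(),
                      correct = TRUE) {
  n <- length(congruent) + length(incongruent) + length(neutral)
  tibble::tibble(
    pair_type = rep(c("angry-neutral", "angry-neutral", "neutral-neutral"),
                    c(length(congruent), length(incongruent),
                      length(neutral))),
    probe_at_angry_location = rep(c(TRUE, FALSE, NA),
                                  c(length(congruent), length(incongruent),
                                    length(neutral))),
    rt_ms = c(congruent, incongruent, neutral),
    correct = rep_len(correct, n)
  )
}

# Independent brute-force bias scorer: applies the three exclusion rules
# from scratch with naive loops, then averages.
brute_bias <- function(trials) {
  cond <- ifelse(trials$pair_type == "neutral-neutral", "neutral",
                 ifelse(trials$probe_at_angry_location, "con", "inc"))
  keep <- trials$correct & trials$rt_ms >= 150
  for (cc in unique(cond)) {
    i <- which(keep & cond == cc)
    m <- mean(trials$rt_ms[i]); s <- stats::sd(trials$rt_ms[i])
    for (j in i) {
      if (abs(trials$rt_ms[j] - m) > 2 * s) keep[j] <- FALSE
    }
  }
  mean(trials$rt_ms[keep & cond == "inc"]) -
    mean(trials$rt_ms[keep & cond == "con"])
}
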