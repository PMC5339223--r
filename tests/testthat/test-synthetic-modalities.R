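lat <- generate_latent(seed = 11)

test_that("noiseless BOLD equals the convolved latent and a constant stays constant", {
  b <- generate_bold(lat, n_coupled = 1, n_null = 0, snr = Inf, seed = 1)
  expect_equal(as.numeric(b$voxels[1, ]), b$clean_roi$value)
  expect_equal(b$roi$value, b$clean_roi$value)
  flat <- generate_latent(latent_profile(bump_amplitude = 0, baseline = 2),
                          seed = 1)
  bf <- generate_bold(flat, n_coupled = 1, n_null = 0, snr = Inf, seed = 1)
  expect_equal(tail(bf$clean_roi$value, 90), rep(2, 90), tolerance = 1e-8)
  expect_error(generate_bold(sampled_series(1:2, rate_hz = 1), tr_s = 5),
               class = "angerefp_invalid_argument")
})

test_that("EEG features track the latent exactly as the weights dictate", {
  cp <- coupling_spec()
  zero_w <- cp$eeg_weights * 0
  zero_w["F8", 1, 1] <- 1e-9 # keep the unique-maximum invariant
  cp0 <- coupling_spec(eeg_weights = zero_w)
  e0 <- generate_eeg(lat, cp0, seed = 3)
  lf <- angerefp:::latent_frames(lat, 3)
  rs <- apply(unclass(e0)["F3", , ], 1, cor, y = lf)
  expect_true(all(abs(rs) < 0.35)) # pure noise: no systematic coupling
  # single nonzero weight at delay 0, noiseless: feature is the latent
  w1 <- zero_w
  w1["F8", 3, 1] <- 1
  cp1 <- coupling_spec(eeg_weights = w1, eeg_snr = Inf)
  e1 <- generate_eeg(lat, cp1, seed = 3)
  expect_equal(cor(unclass(e1)["F8", 3, ], lf), 1, tolerance = 1e-12)
  expect_error(generate_eeg(sampled_series(1:30, 10), cp),
               class = "angerefp_invalid_argument")
})

test_that("coupling spec rejects ambiguous electrode dominance", {
  w <- coupling_spec()$eeg_weights
  w["F4", , ] <- w["F8", , ]
  expect_error(coupling_spec(eeg_weights = w),
               class = "angerefp_invalid_argument")
  expect_error(coupling_spec(bold_snr = 0),
               class = "angerefp_invalid_argument")
})

test_that("R-peaks follow the instantaneous rate rule", {
  flat <- generate_latent(latent_profile(bump_amplitude = 0), seed = 1)
  p60 <- generate_rr(flat, base_bpm = 60, hr_gain = 0, jitter_sd_s = 0, seed = 1)
  expect_equal(p60, 0:320)
  p120 <- generate_rr(flat, base_bpm = 120, hr_gain = 0, jitter_sd_s = 0, seed = 1)
  expect_equal(diff(p120), rep(0.5, length(p120) - 1))
  expect_true(all(diff(generate_rr(lat, seed = 2)) > 0))
  expect_error(generate_rr(lat, base_bpm = 5, hr_gain = -100),
               class = "angerefp_invalid_argument")
})

test_that("ratings are the quantized lagged latent on the 21-level grid", {
  r <- generate_rating(lat, lag_s = 0, noise_sd = 0, map = c(0, 1), seed = 1)
  expect_equal(r$value, pmin(pmax(round(lat$value), 0), 20))
  expect_true(all(r$value == round(r$value)))
  flat <- generate_latent(latent_profile(bump_amplitude = 0, baseline = 1),
                          seed = 1)
  rf <- generate_rating(flat, noise_sd = 0, seed = 1)
  expect_equal(length(unique(rf$value)), 1)
})

test_that("every modality's latent coupling is monotone in its gain or SNR", {
  lf <- angerefp:::latent_frames(lat, 3)
  eeg_r <- vapply(c(0.3, 1.5, 8), function(snr) {
    e <- generate_eeg(lat, coupling_spec(eeg_snr = snr), seed = 5)
    abs(cor(unclass(e)["F8", 3, ], lf))
  }, numeric(1))
  expect_true(all(diff(eeg_r) > 0))
  bold_r <- vapply(c(0.3, 1.5, 8), function(snr) {
    b <- generate_bold(lat, n_coupled = 1, n_null = 0, snr = snr, seed = 5)
    cor(b$roi$value, b$clean_roi$value)
  }, numeric(1))
  expect_true(all(diff(bold_r) > 0))
  hr_r <- vapply(c(2, 8, 25), function(gain) {
    hr <- rr_to_hr(generate_rr(lat, hr_gain = gain, seed = 5),
                   duration_s = 321)
    cor(hr$value, angerefp:::series_at(lat, hr$time_s))
  }, numeric(1))
  expect_true(all(diff(hr_r) > 0))
})

test_that("dot-probe trials encode the planted bias and exercise exclusions", {
  # no bias, no errors, no guesses -> scored bias ~ 0
  clean <- generate_dotprobe(true_bias_ms = 0, error_rate = 0,
                             rt_params = list(meanlog = log(520),
                                              sdlog = 0.1, guess_rate = 0),
                             seed = 2)
  expect_lt(abs(score_bias(clean)$bias_ms), 12)
  # calibration at the published vigilance / avoidance group means
  for (bias in c(18.7, -15.1)) {
    big <- generate_dotprobe(n_congruent = 20000, n_incongruent = 20000,
                             n_neutral_pairs = 100, true_bias_ms = bias,
                             seed = 3)
    expect_equal(score_bias(big)$bias_ms, bias, tolerance = 2)
  }
  expect_error(generate_dotprobe(error_rate = 1),
               class = "angerefp_invalid_argument")
})

test_that("outcome draws honour the requested correlation structure", {
  big <- generate_outcomes(seed = 4, n = 100000)
  st <- outcome_structure()
  expect_lt(abs(cor(big$state_anger, big$efp_high) - st$r_sa_efp), 0.01)
  expect_lt(abs(cor(big$state_anger, big$ptss_raw) - st$r_sa_ptss), 0.01)
  expect_lt(abs(cor(big$efp_high, big$ptss_raw) - st$r_efp_ptss), 0.01)
  expect_true(all(big$ptss >= 17 & big$ptss <= 85))
  expect_true(all(big$ptss == round(big$ptss)))
  # uncorrelated structure -> regression betas ~ 0
  null <- generate_outcomes(outcome_structure(0, 0, 0), seed = 5, n = 20000)
  fit <- hierarchical_regression(null, "ptss_raw",
                                 list("state_anger", "efp_high"))
  expect_true(all(abs(tidy(fit)$beta) < 0.02))
  expect_error(outcome_structure(0.9, -0.9, 0.9),
               class = "angerefp_invalid_argument")
})

test_that("generators are bit-reproducible under a fixed seed", {
  cp <- coupling_spec()
  expect_identical(generate_eeg(lat, cp, seed = 9),
                   generate_eeg(lat, cp, seed = 9))
  expect_identical(generate_bold(lat, 2, 2, seed = 9)$voxels,
                   generate_bold(lat, 2, 2, seed = 9)$voxels)
  expect_identical(generate_rr(lat, seed = 9), generate_rr(lat, seed = 9))
  expect_identical(generate_dotprobe(seed = 9), generate_dotprobe(seed = 9))
  expect_identical(generate_outcomes(seed = 9), generate_outcomes(seed = 9))
})
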