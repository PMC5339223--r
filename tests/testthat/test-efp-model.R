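make_design_tf <- function(n_frames = 60, n_bands = 3, seed = 1) {
  withr::with_seed(seed, {
    vals <- array(rnorm(1 * n_bands * n_frames), c(1, n_bands, n_frames))
  })
  tiny_tf(vals)
}

test_that("ridge at lambda 0 on a tall full-rank design equals least squares", {
  tf <- make_design_tf()
  X <- embed_delays(tf, "ch01", 2)
  withr::with_seed(2, y <- rnorm(nrow(X)))
  fit <- angerefp:::ridge_std(X, y, 0)
  Z <- scale(X)
  ols <- lm(y ~ Z) # independent oracle
  expect_equal(fit$beta, unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
})

test_that("a target exactly linear in the design is fit with held-out r near 1", {
  tf <- make_design_tf(n_frames = 80)
  X <- embed_delays(tf, "ch01", 2)
  beta_true <- c(1, -0.5, 0.3, 0.8, 0, 2)
  y <- as.numeric(X %*% beta_true) + 3
  bold <- sampled_series(c(rep(y[1], 1), y), rate_hz = 1 / 3)
  m <- fit_efp_individual(tf, bold, "ch01", delays_frames = 2)
  expect_gt(m$cv_fit_r, 0.999)
  expect_equal(m$ridge_lambda, min(default_lambda_grid()))
})

test_that("the coefficient norm is non-increasing along the ridge path", {
  tf <- make_design_tf(seed = 3)
  X <- embed_delays(tf, "ch01", 2)
  withr::with_seed(4, y <- rnorm(nrow(X)))
  norms <- vapply(10^seq(-3, 3, by = 0.5), function(lam) {
    sqrt(sum(angerefp:::ridge_std(X, y, lam)$beta^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("predictions are invariant to affine rescaling of raw features", {
  tf <- make_design_tf(n_frames = 70, seed = 5)
  withr::with_seed(6, y <- rnorm(68))
  bold <- sampled_series(c(0, 0, y), rate_hz = 1 / 3)
  m1 <- fit_efp_individual(tf, bold, "ch01", delays_frames = 3)
  scaled <- unclass(tf)
  scaled[1, 1, ] <- 5 * scaled[1, 1, ] - 2
  scaled[1, 2, ] <- 0.1 * scaled[1, 2, ] + 40
  tf2 <- tiny_tf(scaled)
  m2 <- fit_efp_individual(tf2, bold, "ch01", delays_frames = 3)
  expect_equal(predict_efp(tf2, m2, 1 / 3)$value,
               predict_efp(tf, m1, 1 / 3)$value, tolerance = 1e-8)
  expect_equal(m1$cv_fit_r, m2$cv_fit_r, tolerance = 1e-10)
})

test_that("fitting requires enough frames and a non-degenerate design", {
  tf <- make_design_tf(n_frames = 12)
  bold <- sampled_series(rnorm(12), rate_hz = 1 / 3)
  expect_error(fit_efp_individual(tf, bold, "ch01", 2),
               class = "angerefp_invalid_argument")
  const <- tiny_tf(array(1, c(1, 2, 40)))
  boldc <- sampled_series(rnorm(40), rate_hz = 1 / 3)
  expect_error(fit_efp_individual(const, boldc, "ch01", 2),
               class = "angerefp_invalid_argument")
})

test_that("model clustering keeps the tight high-performing cluster", {
  mk <- function(core, jitter, fit) {
    manual_model(core + matrix(rnorm(12, 0, jitter), 3, 4), cv_fit_r = fit)
  }
  withr::with_seed(8, {
    base_a <- matrix(rnorm(12), 3, 4)
    base_b <- -base_a + matrix(rnorm(12, 0, 0.2), 3, 4)
    good <- lapply(c(0.6, 0.65, 0.7), function(f) mk(base_a, 0.05, f))
    weak <- lapply(c(0.2, 0.25, 0.3), function(f) mk(base_b, 0.05, f))
  })
  sel <- cluster_efp_models(c(good, weak))
  expect_length(sel, 3)
  expect_equal(vapply(sel, function(m) m$cv_fit_r, numeric(1)),
               c(0.6, 0.65, 0.7))
  # all-identical models come back whole
  same <- replicate(4, manual_model(base_a, 0.5), simplify = FALSE)
  expect_length(cluster_efp_models(same), 4)
  # a lone outlier is excluded at any cut below its linkage height
  outlier <- manual_model(base_b, cv_fit_r = 0.9)
  sel2 <- cluster_efp_models(c(good, list(outlier)), cut_height = 0.5)
  expect_length(sel2, 3)
  expect_false(any(vapply(sel2, function(m) m$cv_fit_r == 0.9, logical(1))))
  expect_error(cluster_efp_models(good[1:2]),
               class = "angerefp_invalid_argument")
})

test_that("identical subjects give a common model equal to the individual fit", {
  tf <- make_design_tf(n_frames = 60, seed = 9)
  X <- embed_delays(tf, "ch01", 2)
  y <- as.numeric(X %*% c(1, 0.5, -1, 0.2, 0.7, -0.3))
  bold <- sampled_series(c(y[1], y), rate_hz = 1 / 3)
  ind <- fit_efp_individual(tf, bold, "ch01", 2)
  com <- fit_efp_common(list(tf, tf, tf), list(bold, bold, bold), "ch01", 2)
  # same standardized problem per subject -> proportional coefficients;
  # compare prediction series (scale-free)
  expect_equal(cor(predict_efp(tf, com, 1 / 3)$value,
                   predict_efp(tf, ind, 1 / 3)$value), 1, tolerance = 1e-6)
  expect_warning(fit_efp_common(list(tf), list(bold), "ch01", 2),
                 "single subject")
})

test_that("applying a model reproduces the stated binning arithmetic", {
  grid0 <- matrix(0, 2, 2)
  tf <- make_design_tf(n_frames = 107, n_bands = 2, seed = 11)
  m0 <- manual_model(grid0, electrode = "ch01", intercept = 1.5)
  s <- predict_efp(tf, m0)
  expect_equal(nrow(s), 9) # 107 frames / 12-frame bins -> 9 samples
  expect_equal(s$value, rep(1.5, 9))
  expect_equal(series_rate(s), 1 / 36)
  # output at the frame rate means no binning
  s_full <- predict_efp(tf, m0, output_rate_hz = 1 / 3)
  expect_equal(nrow(s_full), 107)
  m_wrong <- manual_model(grid0, electrode = "F9")
  expect_error(predict_efp(tf, m_wrong), "available")
})

test_that("the common model recovers structure on generator data", {
  lat <- generate_latent(seed = 21)
  cp <- coupling_spec()
  subs <- lapply(1:8, function(i) cohort_pair(3000 + i, lat, cp))
  tfs <- lapply(subs, `[[`, "eeg")
  rois <- lapply(subs, function(s) s$bold$roi)
  com <- fit_efp_common(tfs[1:6], rois[1:6], "F8")
  ind_r <- vapply(1:6, function(i) {
    fit_efp_individual(tfs[[i]], rois[[i]], "F8")$cv_fit_r
  }, numeric(1))
  # shared true weights, independent noise: pooling beats the median subject
  expect_gt(com$cv_fit_r, median(ind_r))
  held <- vapply(7:8, function(i) {
    cor(predict_efp(tfs[[i]], com, 1 / 3)$value,
        subs[[i]]$bold$clean_roi$value)
  }, numeric(1))
  expect_gt(mean(held), 0.4)
  # high-anger window mean exceeds low-anger for coupled subjects
  efp <- predict_efp(tfs[[7]], com)
  expect_gt(window_mean(efp, window_spec("high", 189, 289)),
            window_mean(efp, window_spec("low", 0, 100)))
})

test_that("electrode selection finds the informative channel", {
  # constructed fixture: one informative channel, the rest pure noise
  lat <- generate_latent(seed = 22)
  cp <- coupling_spec()
  w <- cp$eeg_weights * 0
  w["F4", , ] <- cp$eeg_weights["F8", , ]
  cpx <- coupling_spec(eeg_weights = w, target_electrode = "F4")
  subs <- lapply(1:5, function(i) {
    list(eeg = generate_eeg(lat, cpx, seed = 400 + i),
         bold = generate_bold(lat, 10, 0, snr = 1, seed = 900 + i)$roi)
  })
  sel <- select_electrode(lapply(subs, `[[`, "eeg"),
                          lapply(subs, `[[`, "bold"))
  expect_equal(sel$electrode, "F4")
  expect_error(select_electrode(lapply(subs, `[[`, "eeg")[1],
                                lapply(subs, `[[`, "bold")[1],
                                channels = "F4"),
               class = "angerefp_invalid_argument")
})
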