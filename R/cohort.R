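#' Simulate a full multimodal cohort
#'
#' Generates, for every subject, the modalities the analysis pipeline
#' consumes -- EEG band-power tensor, ROI BOLD, R-peak times, continuous
#' anger rating, dot-probe trials -- all driven by one shared latent
#' anger-intensity trace (the film), plus a between-subject outcome table
#' (state-anger, fingerprint window mean, PTSS) drawn from the reference
#' correlation structure. Per-subject randomness is drawn from seeds
#' derived deterministically from `seed`, so the whole cohort is
#' reproducible bit for bit.
#'
#' Each subject also receives a ground-truth attention bias drawn from
#' `N(bias_mean_ms, bias_sd_ms)`, producing both vigilance and avoidance
#' subjects; no systematic bias-group difference in fingerprint coupling
#' is simulated (the group factor is exposed to the ANOVA as measured, not
#' planted).
#'
#' @param n_subjects Number of subjects.
#' @param seed Master integer seed.
#' @param profile Latent profile, see [latent_profile()].
#' @param coupling Coupling ground truth, see [coupling_spec()].
#' @param outcome Outcome structure, see [outcome_structure()].
#' @param n_coupled,n_null BOLD voxels per subject.
#' @param base_bpm Baseline heart rate.
#' @param bias_mean_ms,bias_sd_ms Population of true attention biases.
#' @return An `anger_cohort` list: `subjects` (outcome tibble with
#'   `true_bias_ms`), `latent`, and per-subject lists `eeg`, `bold`,
#'   `rpeaks`, `ratings`, plus a combined `dotprobe` trial tibble.
#' @export
simulate_cohort <- function(n_subjects = 20, seed = 1,
                            profile = latent_profile(),
                            coupling = coupling_spec(),
                            outcome = outcome_structure(n_subjects = n_subjects),
                            n_coupled = 10, n_null = 10,
                            base_bpm = 70, bias_mean_ms = 2,
                            bias_sd_ms = 18) {
  if (n_subjects < 1) abort_invalid("`n_subjects` must be >= 1.")
  latent <- generate_latent(profile, seed = seed)
  sub_seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1, n_subjects * 5),
           n_subjects, 5)
  })
  true_bias <- withr::with_seed(seed + 1,
                                rnorm(n_subjects, bias_mean_ms, bias_sd_ms))
  ids <- sprintf("sub-%03d", seq_len(n_subjects))
  eeg <- bold <- rpeaks <- ratings <- vector("list", n_subjects)
  dot <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    eeg[[i]] <- generate_eeg(latent, coupling, frame_s = coupling$frame_s,
                             seed = sub_seeds[i, 1])
    bold[[i]] <- generate_bold(latent, n_coupled, n_null,
                               tr_s = coupling$frame_s,
                               snr = coupling$bold_snr,
                               seed = sub_seeds[i, 2])
    rpeaks[[i]] <- generate_rr(latent, base_bpm = base_bpm,
                               hr_gain = coupling$hr_gain,
                               seed = sub_seeds[i, 3])
    ratings[[i]] <- generate_rating(latent, lag_s = coupling$rating_lag_s,
                                    noise_sd = coupling$rating_noise_sd,
                                    seed = sub_seeds[i, 4])
    dot[[i]] <- generate_dotprobe(true_bias_ms = true_bias[i],
                                  seed = sub_seeds[i, 5]) %>%
      mutate(subject = ids[i], .before = 1)
  }
  subjects <- generate_outcomes(outcome, seed = seed + 2, n = n_subjects) %>%
    mutate(true_bias_ms = true_bias)
  names(eeg) <- names(bold) <- names(rpeaks) <- names(ratings) <- ids
  structure(
    list(subjects = subjects, latent = latent, eeg = eeg, bold = bold,
         rpeaks = rpeaks, ratings = ratings, dotprobe = bind_rows(dot),
         profile = profile, coupling = coupling, outcome = outcome,
         seed = seed, n_subjects = n_subjects),
    class = "anger_cohort"
  )
}

#' @export
print.anger_cohort <- function(x, ...) {
  cat(sprintf(
    "<anger_cohort: %d subjects, %.0f s recording, seed %d>\n",
    x$n_subjects, nrow(x$latent) / series_rate(x$latent), x$seed))
  invisible(x)
}

#' Group rating and heart-rate traces of a cohort
#'
#' Overlay of the group-mean anger rating and heart rate with the low- and
#' high-anger windows shaded.
#'
#' @param object An `anger_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anger_cohort <- function(object, ...) {
  rating <- group_mean_trace(object$ratings)
  duration <- nrow(object$latent) / series_rate(object$latent)
  hr <- group_mean_trace(lapply(object$rpeaks, rr_to_hr,
                                duration_s = duration))
  win <- find_windows(rating)
  df <- bind_rows(
    mutate(rating, value = as.numeric(scale(.data$value)),
           modality = "anger rating"),
    mutate(hr, value = as.numeric(scale(.data$value)),
           modality = "heart rate")
  )
  shade <- tibble(
    label = c(win$low$label, win$high$label),
    xmin = c(win$low$onset_s, win$high$onset_s),
    xmax = c(win$low$offset_s, win$high$offset_s)
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    alpha = .data$label),
                       fill = "grey40", show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(0.15, 0.3)) +
    ggplot2::geom_line(ggplot2::aes(x = .data$time_s, y = .data$value,
                                    colour = .data$modality)) +
    ggplot2::labs(x = "time (s)", y = "group mean (z)", colour = NULL) +
    ggplot2::theme_minimal()
}
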