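#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage end to end: simulate the cohort and write it out,
#' locate the low-/high-anger windows from the group rating trace, select
#' the electrode and fit the common fingerprint model, extract per-subject
#' fingerprint series and window means, build heart-rate series and the
#' rating/HR coupling statistics, run the paired window tests, score the
#' dot-probe biases and the group-by-period mixed ANOVA, fit the
#' hierarchical PTSS regression, and reconstruct the reference regression
#' tables. All outputs are plain text (TSV/JSON) under `out_dir`; rerunning
#' with the same seed and parameters rewrites byte-identical files.
#'
#' @param out_dir Output directory.
#' @param n_subjects Cohort size.
#' @param seed Master seed.
#' @param blocks Regression blocks for the PTSS model.
#' @param ... Passed to [simulate_cohort()].
#' @return A list with every stage's result, invisibly.
#' @export
run_pipeline <- function(out_dir, n_subjects = 20, seed = 1,
                         blocks = list("state_anger", "efp_high"), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(n_subjects = n_subjects, seed = seed, ...)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  duration <- nrow(cohort$latent) / series_rate(cohort$latent)
  ids <- cohort$subjects$subject

  # behavioral windows
  mean_rating <- group_mean_trace(cohort$ratings)
  windows <- find_windows(mean_rating)
  jsonlite::write_json(
    lapply(windows, function(w) list(label = w$label, onset_s = w$onset_s,
                                     offset_s = w$offset_s)),
    file.path(out_dir, "windows.json"), auto_unbox = TRUE, digits = NA)

  # fingerprint: electrode selection + common model + per-subject series
  bolds <- lapply(cohort$bold, `[[`, "roi")
  sel <- select_electrode(cohort$eeg, bolds)
  model <- sel$model
  write_efp_model(model, file.path(out_dir, "efp_model.json"))
  efp <- lapply(cohort$eeg, predict_efp, model = model)
  efp_windows <- tibble(
    subject = ids,
    efp_low_measured = vapply(efp, window_mean, numeric(1),
                              window = windows$low),
    efp_high_measured = vapply(efp, window_mean, numeric(1),
                               window = windows$high)
  )
  write_tsv0(efp_windows, file.path(out_dir, "efp_windows.tsv"))

  # psychophysiology
  hr <- lapply(cohort$rpeaks, rr_to_hr, duration_s = duration)
  hr_cpl <- coupling_stats(hr, cohort$ratings)
  efp_cpl <- coupling_stats(efp, cohort$ratings)
  paired <- bind_rows(
    mutate(paired_window_test(
      vapply(cohort$ratings, window_mean, numeric(1), window = windows$low),
      vapply(cohort$ratings, window_mean, numeric(1), window = windows$high)),
      measure = "anger_rating", .before = 1),
    mutate(paired_window_test(
      vapply(hr, window_mean, numeric(1), window = windows$low),
      vapply(hr, window_mean, numeric(1), window = windows$high)),
      measure = "heart_rate", .before = 1)
  )
  write_tsv0(paired, file.path(out_dir, "paired_window_tests.tsv"))
  jsonlite::write_json(
    list(hr_vs_rating = unclass(glance(hr_cpl)),
         efp_vs_rating = unclass(glance(efp_cpl))),
    file.path(out_dir, "coupling.json"), auto_unbox = TRUE, digits = NA)

  # attention bias + mixed ANOVA on measured fingerprint window means
  bias <- score_bias_cohort(cohort$dotprobe)
  write_tsv0(bias, file.path(out_dir, "bias.tsv"))
  anova_data <- bias %>%
    filter(.data$scorable) %>%
    select("subject", "group") %>%
    left_join(efp_windows, by = "subject") %>%
    rename(low = "efp_low_measured", high = "efp_high_measured")
  anova_res <- tryCatch(
    mixed_anova(anova_data),
    angerefp_invalid_argument = function(e) {
      inform(paste("mixed ANOVA skipped:", conditionMessage(e)))
      NULL
    })
  jsonlite::write_json(
    if (is.null(anova_res)) list(skipped = TRUE) else
      list(effects = anova_res$effects,
           simple_effects = anova_res$simple_effects),
    file.path(out_dir, "anova.json"), digits = NA)

  # PTSS regression (Table-1 shaped TSV) + reference reconstruction
  reg <- hierarchical_regression(cohort$subjects, "ptss", blocks)
  write_tsv0(tidy(reg), file.path(out_dir, "regression.tsv"))
  write_tsv0(reproduce_reference_tables(),
             file.path(out_dir, "reference_tables.tsv"))

  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("angerefp")),
         seed = seed, n_subjects = n_subjects,
         electrode = sel$electrode,
         stage_subject_counts = list(
           eeg = length(cohort$eeg), bold = length(cohort$bold),
           dotprobe_scorable = sum(bias$scorable),
           regression = reg$n)),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, windows = windows, selection = sel,
                 efp = efp, efp_windows = efp_windows, hr = hr,
                 hr_coupling = hr_cpl, efp_coupling = efp_cpl,
                 paired = paired, bias = bias, anova = anova_res,
                 regression = reg))
}
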