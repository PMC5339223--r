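# Cohort directory layout (all plain text):
#   manifest.yaml            generator parameters, seeds, constants, inventory
#   subjects.tsv             one row per subject (outcomes, true bias)
#   dotprobe.tsv             all subjects' trials
#   sub-XXX/eeg_features.tsv long (channel, band, frame, value)
#   sub-XXX/eeg_features.json  channel labels, band edges (Hz), frame length
#   sub-XXX/bold.tsv         (time_s, roi) ROI-mean BOLD
#   sub-XXX/rpeaks.tsv       one column of seconds
#   sub-XXX/rating.tsv       (time_s, level)

write_tsv0 <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv0 <- function(path) {
  as_tibble(read.delim(path, sep = "\t", check.names = FALSE))
}

#' Write a cohort to a plain-text directory
#'
#' Serializes the tabular modalities as TSV with JSON sidecars and records
#' every generator parameter and seed in `manifest.yaml`. Voxel-level BOLD
#' matrices are not serialized (only the ROI mean); voxel-wise analyses
#' operate on the in-memory cohort.
#'
#' @param cohort An `anger_cohort`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "anger_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv0(cohort$subjects, file.path(dir, "subjects.tsv"))
  write_tsv0(cohort$dotprobe, file.path(dir, "dotprobe.tsv"))
  ids <- cohort$subjects$subject
  inventory <- list()
  for (id in ids) {
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    tf <- cohort$eeg[[id]]
    write_tsv0(tidy(tf)[, c("channel", "band", "frame", "value")],
               file.path(sdir, "eeg_features.tsv"))
    jsonlite::write_json(
      list(channel_labels = tf_channels(tf),
           band_edges_hz = attr(tf, "band_edges_hz"),
           frame_s = tf_frame_s(tf), start_s = tf_start_s(tf)),
      file.path(sdir, "eeg_features.json"), auto_unbox = TRUE, digits = NA)
    roi <- cohort$bold[[id]]$roi
    write_tsv0(tibble(time_s = roi$time_s, roi = roi$value),
               file.path(sdir, "bold.tsv"))
    write_tsv0(tibble(rpeak_s = cohort$rpeaks[[id]]),
               file.path(sdir, "rpeaks.tsv"))
    rt <- cohort$ratings[[id]]
    write_tsv0(tibble(time_s = rt$time_s, level = rt$value),
               file.path(sdir, "rating.tsv"))
    inventory[[id]] <- c("eeg_features.tsv", "eeg_features.json",
                         "bold.tsv", "rpeaks.tsv", "rating.tsv")
  }
  manifest <- list(
    schema_version = 1,
    seed = cohort$seed,
    n_subjects = cohort$n_subjects,
    constants = list(tr_s = cohort$coupling$frame_s,
                     eeg_frame_s = cohort$coupling$frame_s,
                     rating_rate_hz = 10, efp_rate_hz = 0.03,
                     hr_bin_s = 1),
    profile = unclass(cohort$profile),
    coupling = list(
      channel_labels = cohort$coupling$channel_labels,
      band_edges_hz = cohort$coupling$band_edges_hz,
      target_electrode = cohort$coupling$target_electrode,
      bold_snr = cohort$coupling$bold_snr,
      eeg_snr = cohort$coupling$eeg_snr,
      hr_gain = cohort$coupling$hr_gain,
      rating_lag_s = cohort$coupling$rating_lag_s,
      rating_noise_sd = cohort$coupling$rating_noise_sd
    ),
    files = inventory
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort directory
#'
#' Reconstructs the tabular parts of a cohort written by [write_cohort()]:
#' subjects, dot-probe trials, EEG tensors, ROI BOLD series, R-peaks and
#' ratings. Voxel matrices are not round-tripped.
#'
#' @param dir Cohort directory.
#' @return A list mirroring the `anger_cohort` slots that were serialized.
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  subjects <- read_tsv0(file.path(dir, "subjects.tsv"))
  dotprobe <- read_tsv0(file.path(dir, "dotprobe.tsv"))
  ids <- subjects$subject
  eeg <- bold <- rpeaks <- ratings <- setNames(vector("list", length(ids)),
                                               ids)
  for (id in ids) {
    sdir <- file.path(dir, id)
    side <- jsonlite::read_json(file.path(sdir, "eeg_features.json"),
                                simplifyVector = TRUE)
    long <- read_tsv0(file.path(sdir, "eeg_features.tsv"))
    nch <- length(side$channel_labels)
    nb <- length(side$band_edges_hz) - 1
    nf <- max(long$frame)
    arr <- array(NA_real_, c(nch, nb, nf),
                 dimnames = list(side$channel_labels,
                                 band_names(side$band_edges_hz), NULL))
    arr[cbind(match(long$channel, side$channel_labels),
              match(long$band, band_names(side$band_edges_hz)),
              long$frame)] <- long$value
    eeg[[id]] <- eeg_tf(arr, side$band_edges_hz, side$frame_s, side$start_s)
    b <- read_tsv0(file.path(sdir, "bold.tsv"))
    bold[[id]] <- sampled_series(b$roi,
                                 rate_hz = 1 / stats::median(diff(b$time_s)),
                                 start_s = b$time_s[1])
    rpeaks[[id]] <- read_tsv0(file.path(sdir, "rpeaks.tsv"))$rpeak_s
    r <- read_tsv0(file.path(sdir, "rating.tsv"))
    ratings[[id]] <- sampled_series(r$level, rate_hz = manifest$constants$rating_rate_hz,
                                    start_s = r$time_s[1])
  }
  list(subjects = subjects, dotprobe = dotprobe, eeg = eeg, bold = bold,
       rpeaks = rpeaks, ratings = ratings, manifest = manifest)
}

#' Serialize a fingerprint model to JSON
#'
#' @param model An `efp_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_efp_model <- function(model, path) {
  stopifnot(inherits(model, "efp_model"))
  jsonlite::write_json(
    list(electrode = model$electrode,
         bands = rownames(model$coefficients),
         band_edges_hz = model$band_edges_hz,
         delays_frames = model$delays_frames,
         frame_s = model$frame_s,
         ridge_lambda = model$ridge_lambda,
         intercept = model$intercept,
         cv_fit_r = model$cv_fit_r,
         training_subject_ids = model$training_subject_ids,
         coefficients = unname(apply(model$coefficients, 1, as.numeric,
                                     simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fingerprint model written by [write_efp_model()]
#'
#' @param path JSON file.
#' @return An `efp_model`.
#' @export
read_efp_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- if (is.matrix(j$coefficients)) j$coefficients else
    do.call(rbind, j$coefficients)
  new_efp_model(as.vector(t(grid)), j$intercept, j$ridge_lambda, j$bands,
                j$delays_frames, j$electrode, j$cv_fit_r, j$band_edges_hz,
                j$frame_s, j$training_subject_ids)
}
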