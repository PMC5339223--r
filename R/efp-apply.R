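#' Apply a fingerprint model to an EEG tensor
#'
#' Produces the frame-rate fingerprint prediction (features are
#' standardized within the recording, matching how the model was trained)
#' and then averages non-overlapping bins of
#' `ceiling(1 / (output_rate_hz * frame_s))` frames down to the output
#' rate; a trailing partial bin is kept. The default 0.03 Hz output
#' corresponds to 33.3-s bins of a 3-s-frame prediction, e.g. 9 samples
#' for a 321-s recording.
#'
#' @param tf An `eeg_tf` tensor containing the model's electrode.
#' @param model An `efp_model`.
#' @param output_rate_hz Output sampling rate; equal to the frame rate
#'   means no binning.
#' @return A sampled series tibble.
#' @export
predict_efp <- function(tf, model, output_rate_hz = 0.03) {
  stopifnot(inherits(model, "efp_model"))
  if (!model$electrode %in% tf_channels(tf)) {
    abort_invalid(sprintf(
      "electrode '%s' missing from tensor (available: %s).",
      model$electrode, paste(tf_channels(tf), collapse = ", ")))
  }
  frame_s <- tf_frame_s(tf)
  X <- embed_delays(tf, model$electrode, model$delays_frames, pad = TRUE)
  Z <- std_apply(X, std_stats(X))
  beta <- as.vector(t(model$coefficients)) # bands-major, matching embed
  pred <- model$intercept + as.numeric(Z %*% beta)
  frame_rate <- 1 / frame_s
  if (abs(output_rate_hz - frame_rate) < 1e-9) {
    return(sampled_series(pred, rate_hz = frame_rate,
                          start_s = tf_start_s(tf)))
  }
  bin <- ceiling(1 / (output_rate_hz * frame_s))
  grp <- (seq_along(pred) - 1) %/% bin
  out <- as.numeric(tapply(pred, grp, mean))
  sampled_series(out, rate_hz = 1 / (bin * frame_s),
                 start_s = tf_start_s(tf))
}

#' @describeIn tidy.efp_model One row per (band, delay) coefficient.
#' @export
tidy.efp_model <- function(x, ...) {
  grid <- x$coefficients
  tibble(
    band = rep(rownames(grid), times = ncol(grid)),
    lag_frames = rep(seq_len(ncol(grid)) - 1, each = nrow(grid)),
    lag_s = rep((seq_len(ncol(grid)) - 1) * x$frame_s, each = nrow(grid)),
    estimate = as.vector(grid)
  )
}

#' Glance at a fingerprint model
#'
#' @param x An `efp_model`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.efp_model <- function(x, ...) {
  tibble(
    electrode = x$electrode,
    n_bands = nrow(x$coefficients),
    delays_frames = x$delays_frames,
    ridge_lambda = x$ridge_lambda,
    cv_fit_r = x$cv_fit_r,
    n_training_subjects = length(x$training_subject_ids %||% character())
  )
}

#' Coefficient-grid heatmap of a fingerprint model
#'
#' @param object An `efp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.efp_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s,
                                   y = factor(.data$band,
                                              levels = rev(rownames(object$coefficients))),
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "EEG lag behind BOLD (s)", y = NULL,
                  fill = "coefficient",
                  title = sprintf("Fingerprint coefficients, electrode %s",
                                  object$electrode)) +
    ggplot2::theme_minimal()
}
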