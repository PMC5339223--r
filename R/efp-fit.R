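# Ridge regression on standardized variables.  Columns of X are centred and
# scaled (constant columns are zeroed), y is centred; the coefficient vector
# solves (Z'Z + lambda I) b = Z'y, so lambda = 0 reproduces ordinary least
# squares on the standardized design.
ridge_std <- function(X, y, lambda) {
  sc <- std_stats(X)
  Z <- std_apply(X, sc)
  yc <- y - mean(y)
  p <- ncol(Z)
  b <- tryCatch(
    solve(crossprod(Z) + diag(lambda, p), crossprod(Z, yc)),
    error = function(e) abort_invalid("design matrix has rank 0 (or is singular at lambda = 0).")
  )
  list(beta = as.numeric(b), intercept = mean(y), scale = sc)
}

std_stats <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s < 1e-12] <- Inf # constant column -> zeroed
  list(mean = m, sd = s)
}

std_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$mean, "-"), 2, sc$sd, "/")
}

safe_cor <- function(a, b) {
  if (sd(a) < 1e-12 || sd(b) < 1e-12) return(0)
  cor(a, b)
}

default_lambda_grid <- function() 10^seq(-3, 3, by = 1)

new_efp_model <- function(beta, intercept, lambda, bands, delays_frames,
                          electrode, cv_fit_r, band_edges_hz, frame_s,
                          training_subject_ids = NULL) {
  coef_grid <- matrix(beta, nrow = length(bands), ncol = delays_frames,
                      byrow = TRUE,
                      dimnames = list(bands,
                                      paste0("lag", seq_len(delays_frames) - 1)))
  structure(
    list(electrode = electrode, coefficients = coef_grid,
         intercept = intercept, ridge_lambda = lambda,
         delays_frames = delays_frames, cv_fit_r = cv_fit_r,
         band_edges_hz = band_edges_hz, frame_s = frame_s,
         training_subject_ids = training_subject_ids),
    class = "efp_model"
  )
}

#' @export
print.efp_model <- function(x, ...) {
  cat(sprintf(
    "<efp_model: electrode %s, %d bands x %d delays, lambda = %g, cv r = %.3f>\n",
    x$electrode, nrow(x$coefficients), x$delays_frames, x$ridge_lambda,
    x$cv_fit_r))
  invisible(x)
}

# Align a delay-embedded design with a BOLD series sampled on the frame grid.
align_target <- function(X, bold, frame_s) {
  tr <- 1 / series_rate(bold)
  if (abs(tr - frame_s) > 1e-6) {
    abort_invalid("BOLD sampling interval must equal the EEG frame length.")
  }
  frames <- attr(X, "frames")
  if (max(frames) > nrow(bold)) {
    abort_invalid("BOLD series has fewer frames than the EEG tensor.")
  }
  bold$value[frames]
}

#' Fit an individual electrical-fingerprint model
#'
#' Ridge regression of an ROI BOLD time course on the delay-embedded
#' band-power features of one electrode. The penalty is chosen on a
#' logarithmic grid by blocked (contiguous) k-fold cross-validation
#' maximizing the held-out Pearson correlation -- contiguous folds respect
#' the strong autocorrelation of both signals. `cv_fit_r` records the mean
#' held-out correlation at the chosen penalty.
#'
#' @param tf An `eeg_tf` tensor for the subject.
#' @param bold ROI BOLD sampled series on the same frame grid.
#' @param channel Electrode to use.
#' @param delays_frames Number of frame delays in the design (default 6, at
#'   3-s frames this spans the ~18 s hemodynamic lag).
#' @param lambda_grid Ridge penalties to search.
#' @param folds Number of contiguous CV folds.
#' @param subject_id Optional identifier stored in the model.
#' @return An `efp_model`.
#' @export
fit_efp_individual <- function(tf, bold, channel, delays_frames = 6,
                               lambda_grid = default_lambda_grid(),
                               folds = 5, subject_id = NULL) {
  X <- embed_delays(tf, channel, delays_frames)
  y <- align_target(X, bold, tf_frame_s(tf))
  n <- nrow(X)
  if (n < 20) abort_invalid("need at least 20 aligned frames to fit.")
  if (all(!is.finite(std_stats(X)$sd))) {
    abort_invalid("design matrix has rank 0 (all features constant).")
  }
  fold_id <- cut(seq_len(n), breaks = folds, labels = FALSE)
  cv_r <- vapply(lambda_grid, function(lam) {
    mean(vapply(seq_len(folds), function(k) {
      tr <- fold_id != k
      fit <- ridge_std(X[tr, , drop = FALSE], y[tr], lam)
      pred <- fit$intercept +
        std_apply(X[!tr, , drop = FALSE], fit$scale) %*% fit$beta
      safe_cor(as.numeric(pred), y[!tr])
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(cv_r) # ties: smallest lambda wins (first index)
  fit <- ridge_std(X, y, lambda_grid[best])
  new_efp_model(fit$beta, fit$intercept, lambda_grid[best],
                attr(X, "bands"), delays_frames, channel, cv_r[best],
                attr(tf, "band_edges_hz"), tf_frame_s(tf),
                training_subject_ids = subject_id)
}

#' Select the tightest well-performing cluster of individual models
#'
#' Agglomerative clustering (average linkage) of the flattened coefficient
#' grids under the distance 1 - Pearson r. The dendrogram is cut at
#' `cut_height`; among the clusters with at least two members the one with
#' the highest mean cross-validated fit is returned. An outlier model whose
#' linkage height exceeds the cut is thereby excluded.
#'
#' @param models List of `efp_model` objects with identical grid shapes.
#' @param cut_height Dendrogram cut, on the 1 - r scale (default 0.5).
#' @return The selected sub-list of models, with a `cluster` attribute
#'   giving each input model's cluster index.
#' @export
cluster_efp_models <- function(models, cut_height = 0.5) {
  if (length(models) < 3) abort_invalid("need at least 3 models to cluster.")
  shapes <- vapply(models, function(m) paste(dim(m$coefficients),
                                             collapse = "x"), character(1))
  if (length(unique(shapes)) != 1) {
    abort_invalid("all coefficient grids must share one shape.")
  }
  M <- vapply(models, function(m) as.vector(m$coefficients),
              numeric(length(models[[1]]$coefficients)))
  k <- ncol(M)
  D <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- if (sd(M[, i]) < 1e-12 || sd(M[, j]) < 1e-12) {
        if (max(abs(M[, i] - M[, j])) < 1e-12) 1 else 0
      } else {
        cor(M[, i], M[, j])
      }
      D[i, j] <- D[j, i] <- 1 - r
    }
  }
  cl <- cutree(hclust(stats::as.dist(D), method = "average"),
               h = cut_height)
  sizes <- table(cl)
  eligible <- as.integer(names(sizes)[sizes >= 2])
  if (length(eligible) == 0) {
    warn("no cluster of size >= 2 below the cut; returning the single best model.")
    best <- which.max(vapply(models, function(m) m$cv_fit_r, numeric(1)))
    out <- models[best]
  } else {
    mean_fit <- vapply(eligible, function(g) {
      mean(vapply(models[cl == g], function(m) m$cv_fit_r, numeric(1)))
    }, numeric(1))
    out <- models[cl == eligible[which.max(mean_fit)]]
  }
  attr(out, "cluster") <- cl
  out
}

#' Fit the common fingerprint model across subjects
#'
#' Every subject's delay-embedded design columns and BOLD target are
#' standardized within subject, the rows are stacked, and a single ridge
#' model with shared coefficients is fitted. The penalty is chosen by
#' leave-one-subject-out cross-validation maximizing the mean held-out
#' Pearson correlation, which is also the recorded `cv_fit_r`.
#'
#' @param tfs List of `eeg_tf` tensors, one per subject.
#' @param bolds List of matching ROI BOLD series.
#' @param channel Electrode to use.
#' @param delays_frames,lambda_grid As in [fit_efp_individual()].
#' @param subject_ids Optional identifiers.
#' @return An `efp_model` (intercept 0 on the standardized scale).
#' @export
fit_efp_common <- function(tfs, bolds, channel, delays_frames = 6,
                           lambda_grid = default_lambda_grid(),
                           subject_ids = NULL) {
  stopifnot(length(tfs) == length(bolds))
  ns <- length(tfs)
  if (ns < 1) abort_invalid("need at least one subject.")
  if (ns == 1) {
    warn("single subject: the common model degenerates to an individual fit.")
    return(fit_efp_individual(tfs[[1]], bolds[[1]], channel, delays_frames,
                              lambda_grid, subject_id = subject_ids))
  }
  prep <- lapply(seq_len(ns), function(i) {
    X <- embed_delays(tfs[[i]], channel, delays_frames)
    y <- align_target(X, bolds[[i]], tf_frame_s(tfs[[i]]))
    Z <- std_apply(X, std_stats(X))
    ysd <- sd(y)
    yz <- if (ysd > 1e-12) (y - mean(y)) / ysd else y * 0
    list(Z = Z, y = yz, bands = attr(X, "bands"))
  })
  fit_stack <- function(idx, lam) {
    Z <- do.call(rbind, lapply(prep[idx], `[[`, "Z"))
    y <- unlist(lapply(prep[idx], `[[`, "y"))
    as.numeric(solve(crossprod(Z) + diag(lam, ncol(Z)), crossprod(Z, y)))
  }
  cv_r <- vapply(lambda_grid, function(lam) {
    mean(vapply(seq_len(ns), function(i) {
      b <- fit_stack(setdiff(seq_len(ns), i), lam)
      safe_cor(as.numeric(prep[[i]]$Z %*% b), prep[[i]]$y)
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(cv_r)
  beta <- fit_stack(seq_len(ns), lambda_grid[best])
  new_efp_model(beta, 0, lambda_grid[best], prep[[1]]$bands, delays_frames,
                channel, cv_r[best], attr(tfs[[1]], "band_edges_hz"),
                tf_frame_s(tfs[[1]]), training_subject_ids = subject_ids)
}

#' Cross-validated electrode selection
#'
#' Fits the common model once per candidate electrode and returns the
#' electrode with the highest leave-one-subject-out mean correlation. Ties
#' are broken deterministically by lexical channel order.
#'
#' @param tfs,bolds,delays_frames,lambda_grid As in [fit_efp_common()].
#' @param channels Candidate electrodes; defaults to all channels of the
#'   first tensor.
#' @return An `electrode_selection` list: `electrode`, the winning `model`,
#'   and a `scores` tibble (channel, cv_fit_r, ridge_lambda).
#' @export
select_electrode <- function(tfs, bolds, channels = NULL, delays_frames = 6,
                             lambda_grid = default_lambda_grid()) {
  channels <- channels %||% tf_channels(tfs[[1]])
  if (length(channels) < 2) abort_invalid("need at least 2 candidate electrodes.")
  models <- lapply(channels, function(ch) {
    fit_efp_common(tfs, bolds, ch, delays_frames, lambda_grid)
  })
  scores <- tibble(
    channel = channels,
    cv_fit_r = vapply(models, function(m) m$cv_fit_r, numeric(1)),
    ridge_lambda = vapply(models, function(m) m$ridge_lambda, numeric(1))
  )
  ord <- order(-scores$cv_fit_r, scores$channel)
  best <- ord[1]
  structure(
    list(electrode = channels[best], model = models[[best]],
         scores = scores[ord, ]),
    class = "electrode_selection"
  )
}

#' @export
print.electrode_selection <- function(x, ...) {
  cat(sprintf("<electrode_selection: %s (cv r = %.3f)>\n", x$electrode,
              x$model$cv_fit_r))
  print(x$scores)
  invisible(x)
}
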