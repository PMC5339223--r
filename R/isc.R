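#' Voxel-wise inter-subject correlation with group inference
#'
#' For every voxel, each subject's time course is correlated with the mean
#' time course of all other subjects (leave-one-out); the correlations are
#' Fisher-Z transformed (`atanh`, with |r| clipped to 1 - 1e-7) and a
#' two-sided one-sample t-test against zero across subjects gives the
#' group p-value, optionally Bonferroni-adjusted over voxels. A voxel that
#' is constant in any subject is flagged `NA` and excluded from inference,
#' never silently zeroed. Subject time courses are linearly detrended
#' first (mirroring upstream high-pass filtering) unless `detrend = FALSE`.
#'
#' With `correction = "bonferroni"` the significance mask is
#' `adjusted p < alpha` (adjusted p = min(1, p * V)); an alternative
#' reading that thresholds the raw p at `alpha / V` is numerically
#' identical whenever p * V < 1, and is available via
#' `correction = "none"` with `alpha = alpha / V`.
#'
#' Note that this classical leave-one-out group test is anticonservative
#' under the null because the n leave-one-out correlations are mutually
#' positively correlated (exchangeably, with correlation about 1/(n-1));
#' see the methods vignette for the calibration analysis.
#'
#' @param data Either a list of subject voxel x frame matrices, or a
#'   3-axis array (subject, voxel, frame).
#' @param alpha Significance threshold applied to the (adjusted) p-value.
#' @param correction `"bonferroni"` or `"none"`.
#' @param detrend Remove a per-subject, per-voxel linear trend first.
#' @return An `isc_result` with a per-voxel statistics tibble (`$stats`),
#'   the subject x voxel correlation matrix (`$subject_r`), and the call
#'   parameters.
#' @export
isc_map <- function(data, alpha = 1e-4, correction = c("bonferroni", "none"),
                    detrend = TRUE) {
  correction <- match.arg(correction)
  if (is.array(data) && length(dim(data)) == 3) {
    data <- lapply(seq_len(dim(data)[1]), function(s) data[s, , , drop = TRUE])
  }
  stopifnot(is.list(data))
  ns <- length(data)
  if (ns < 3) abort_invalid("need at least 3 subjects.")
  dims <- vapply(data, dim, numeric(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    abort_invalid("all subjects must share one voxel x frame shape.")
  }
  nv <- dims[1, 1]; nt <- dims[2, 1]
  if (nt < 3) abort_invalid("need at least 3 frames.")
  if (detrend) {
    # remove the least-squares line a + b*t from every (subject, voxel) row
    tt <- seq_len(nt); tc <- tt - mean(tt); den <- sum(tc^2)
    data <- lapply(data, function(m) {
      b <- (m %*% tc) / den
      sweep(m - b %*% t(tc), 1, rowMeans(m), "-")
    })
  }
  # constant-series flag per voxel (any subject)
  const <- Reduce(`|`, lapply(data, function(m) {
    apply(m, 1, function(v) sd(v) < 1e-12)
  }))
  total <- Reduce(`+`, data)
  subject_r <- matrix(NA_real_, ns, nv)
  for (s in seq_len(ns)) {
    x <- data[[s]]
    m <- (total - x) / (ns - 1)
    xc <- x - rowMeans(x)
    mc <- m - rowMeans(m)
    num <- rowSums(xc * mc)
    den <- sqrt(rowSums(xc^2) * rowSums(mc^2))
    r <- ifelse(den > 0, num / den, NA_real_)
    subject_r[s, ] <- r
  }
  subject_r[, const] <- NA_real_
  z <- atanh(pmin(pmax(subject_r, -1 + 1e-7), 1 - 1e-7))
  mean_z <- colMeans(z)
  sd_z <- apply(z, 2, sd)
  t_stat <- mean_z / (sd_z / sqrt(ns))
  t_stat[sd_z < 1e-12 & abs(mean_z) > 0] <- Inf
  df <- ns - 1
  p <- 2 * pt(-abs(t_stat), df)
  p[is.infinite(t_stat)] <- 0
  valid <- !const & is.finite(mean_z)
  v_tested <- sum(valid)
  p_adj <- if (correction == "bonferroni") pmin(1, p * v_tested) else p
  p[!valid] <- NA_real_; p_adj[!valid] <- NA_real_
  t_stat[!valid] <- NA_real_; mean_z[!valid] <- NA_real_
  stats <- tibble(
    voxel = seq_len(nv),
    mean_z = mean_z,
    t = t_stat,
    df = df,
    p = p,
    p_adjusted = p_adj,
    significant = !is.na(p_adj) & p_adj < alpha,
    flagged_constant = const
  )
  structure(
    list(stats = stats, subject_r = subject_r, alpha = alpha,
         correction = correction, n_subjects = ns, n_voxels_tested = v_tested),
    class = "isc_result"
  )
}

#' @export
print.isc_result <- function(x, ...) {
  cat(sprintf(
    "<isc_result: %d subjects, %d voxels tested, %d significant at %s alpha = %g>\n",
    x$n_subjects, x$n_voxels_tested, sum(x$stats$significant),
    x$correction, x$alpha))
  invisible(x)
}

#' @describeIn isc_map Tidy per-voxel statistics.
#' @param x An `isc_result`.
#' @param ... Unused.
#' @export
tidy.isc_result <- function(x, ...) x$stats

#' @describeIn isc_map One-row summary.
#' @export
glance.isc_result <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    n_voxels_tested = x$n_voxels_tested,
    n_significant = sum(x$stats$significant),
    alpha = x$alpha,
    correction = x$correction
  )
}

#' Histogram of voxel-wise group ISC
#'
#' @param object An `isc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isc_result <- function(object, ...) {
  df <- dplyr::filter(object$stats, !.data$flagged_constant)
  ggplot2::ggplot(df, ggplot2::aes(x = tanh(.data$mean_z),
                                   fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 60, boundary = 0) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "mean leave-one-out inter-subject correlation",
                  y = "voxels", fill = "significant") +
    ggplot2::theme_minimal()
}
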