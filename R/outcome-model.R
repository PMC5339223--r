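#' Hierarchical multiple regression with standardized coefficients
#'
#' Predictors are entered in ordered blocks; at each step an ordinary
#' least-squares fit on z-scored variables yields standardized betas,
#' two-sided coefficient p-values (df = n - p - 1), the cumulative
#' R-squared, the R-squared change over the previous step with its F test
#' `dF = ((R2_s - R2_{s-1}) / q) / ((1 - R2_s) / (n - p_s - 1))`, and each
#' predictor's tolerance (1 minus the R-squared of that predictor
#' regressed on its co-predictors in the step). Rows with a missing
#' response or predictor are dropped listwise, and the count is recorded.
#'
#' @param data A data frame.
#' @param response Response column name (string).
#' @param blocks List of character vectors: predictors entered at each
#'   step (cumulative).
#' @return An `hreg` object; see [tidy.hreg()] and [glance.hreg()].
#' @export
hierarchical_regression <- function(data, response, blocks) {
  stopifnot(is.character(response), length(response) == 1, is.list(blocks))
  preds <- unique(unlist(blocks))
  keep <- stats::complete.cases(data[, c(response, preds)])
  n_dropped <- sum(!keep)
  d <- data[keep, ]
  n <- nrow(d)
  if (n <= length(preds) + 1) {
    abort_invalid("need n > number of predictors + 1 after listwise deletion.")
  }
  zscore <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s < 1e-12) abort_invalid("constant variable in model.")
    (v - mean(v)) / s
  }
  z <- as.data.frame(lapply(d[, c(response, preds)], zscore))
  steps <- list()
  r2_prev <- 0
  p_prev <- 0
  for (s in seq_along(blocks)) {
    vars <- unique(unlist(blocks[seq_len(s)]))
    p_s <- length(vars)
    fml <- stats::reformulate(vars, response = response)
    fit <- lm(fml, data = z)
    sm <- summary(fit)
    r2 <- sm$r.squared
    tol <- vapply(vars, function(v) {
      if (p_s == 1) return(1)
      aux <- lm(stats::reformulate(setdiff(vars, v), response = v), data = z)
      1 - summary(aux)$r.squared
    }, numeric(1))
    if (any(tol < 1e-8)) {
      abort_invalid(sprintf("collinear block: tolerance ~ 0 for %s.",
                            paste(vars[tol < 1e-8], collapse = ", ")))
    }
    q <- p_s - p_prev
    dr2 <- r2 - r2_prev
    df2 <- n - p_s - 1
    dF <- (dr2 / q) / ((1 - r2) / df2)
    coefs <- sm$coefficients[vars, , drop = FALSE]
    steps[[s]] <- list(
      step = s, predictors = vars,
      beta = setNames(coefs[, "Estimate"], vars),
      p_value = setNames(coefs[, "Pr(>|t|)"], vars),
      tolerance = tol, r_squared = r2, delta_r_squared = dr2,
      delta_F = dF, delta_F_df = c(q, df2),
      delta_F_p = pf(dF, q, df2, lower.tail = FALSE)
    )
    r2_prev <- r2
    p_prev <- p_s
  }
  structure(list(steps = steps, n = n, n_dropped = n_dropped,
                 response = response),
            class = "hreg")
}

#' @export
print.hreg <- function(x, ...) {
  cat(sprintf("<hierarchical regression of %s: %d step(s), n = %d>\n",
              x$response, length(x$steps), x$n))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a hierarchical regression
#'
#' One row per (step, predictor), shaped like a published regression
#' table: Factors, Beta, p-value, R-squared, Tolerance.
#'
#' @param x An `hreg` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hreg <- function(x, ...) {
  bind_rows(lapply(x$steps, function(s) {
    tibble(step = s$step, term = s$predictors,
           beta = unname(s$beta[s$predictors]),
           p_value = unname(s$p_value[s$predictors]),
           r_squared = s$r_squared,
           tolerance = unname(s$tolerance[s$predictors]))
  }))
}

#' @describeIn tidy.hreg One row per step with the change statistics.
#' @export
glance.hreg <- function(x, ...) {
  bind_rows(lapply(x$steps, function(s) {
    tibble(step = s$step, n_predictors = length(s$predictors),
           r_squared = s$r_squared, delta_r_squared = s$delta_r_squared,
           delta_F = s$delta_F, delta_F_df1 = s$delta_F_df[1],
           delta_F_df2 = s$delta_F_df[2], delta_F_p = s$delta_F_p,
           n = x$n, n_dropped = x$n_dropped)
  }))
}

#' Standardized betas by step
#'
#' @param object An `hreg` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hreg <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$term,
                                   fill = factor(.data$step))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "standardized beta", y = NULL, fill = "step") +
    ggplot2::theme_minimal()
}

#' Reconstruct a two-predictor standardized regression from its betas
#'
#' The standardized normal equations of a two-predictor regression,
#' `r1y = b1 + b2 r12` and `r2y = b2 + b1 r12`, make a published table
#' internally reconstructable from three printed numbers: the step-1 beta
#' (= the first predictor's validity r1y) and the two step-2 betas. The
#' implied predictor intercorrelation is `r12 = (r1y - b1) / b2`, the
#' second validity `r2y = b2 + b1 r12`, the model
#' `R2 = b1 r1y + b2 r2y`, and the tolerance of either predictor
#' `1 - r12^2`.
#'
#' @param r1y Step-1 standardized beta of the first predictor (its
#'   zero-order validity).
#' @param beta1,beta2 Step-2 standardized betas; `beta2` must be nonzero.
#' @return A one-row tibble: `r12`, `r1y`, `r2y`, `r_squared`, `tolerance`.
#' @examples
#' reconstruct_two_predictor(0.454, 0.793, 0.513) # R2 ~ 0.354
#' @export
reconstruct_two_predictor <- function(r1y, beta1, beta2) {
  if (abs(beta2) < 1e-12) abort_invalid("`beta2` must be nonzero.")
  if (abs(r1y) > 1) abort_invalid("|r1y| must be <= 1.")
  r12 <- (r1y - beta1) / beta2
  if (abs(r12) > 1) {
    abort_invalid(sprintf(
      "inconsistent inputs: implied predictor intercorrelation %.3f outside [-1, 1].",
      r12))
  }
  r2y <- beta2 + beta1 * r12
  tibble(r12 = r12, r1y = r1y, r2y = r2y,
         r_squared = beta1 * r1y + beta2 * r2y,
         tolerance = 1 - r12^2)
}

#' Cohen's d
#'
#' One-sample form: `d = mean / SD` (equivalently `t / sqrt(n)`). Pooled
#' two-group form: `(m1 - m2) / s_pooled`. Zero variance returns `NA`.
#'
#' @param x Numeric vector (first group).
#' @param y Optional second group; supplying it selects the pooled form.
#' @param mu Null value subtracted in the one-sample form.
#' @return A single number.
#' @export
cohens_d <- function(x, y = NULL, mu = 0) {
  if (is.null(y)) {
    s <- sd(x)
    if (length(x) < 2 || !is.finite(s) || s < 1e-12) return(NA_real_)
    return((mean(x) - mu) / s)
  }
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort_invalid("need n >= 2 per group.")
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (!is.finite(sp) || sp < 1e-12) return(NA_real_)
  (mean(x) - mean(y)) / sp
}

#' One-sample Cohen's d from a t statistic
#'
#' @param t One-sample t statistic.
#' @param n Sample size.
#' @return `t / sqrt(n)`.
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' Reference standardized-regression coefficients for PTSS prediction
#'
#' The published standardized coefficients of the hierarchical regressions
#' predicting 1-year post-traumatic stress symptoms from the pre-stress
#' anger response in the soldier cohort this package models: state-anger
#' entered at step 1, and one anger-reactivity measure (fingerprint window
#' mean, rating or heart rate) entered at step 2. These printed numbers
#' are the inputs to [reconstruct_two_predictor()].
#'
#' @return A tibble: `table`, `model`, `step2_predictor`, `r1y` (step-1
#'   beta), `beta1`, `beta2`, `reported_r2` (printed step-2 R-squared),
#'   `reported_tolerance`.
#' @export
ptss_reference_models <- function() {
  tibble(
    table = c(1, 1, 1, 2, 2),
    model = c("A", "B", "C", "A", "B"),
    step2_predictor = c("amyg_efp_high", "amyg_efp_low", "ifg_efp_high",
                        "anger_rating_high", "heart_rate_high"),
    r1y = 0.454,
    beta1 = c(0.793, 0.610, 0.542, 0.467, 0.471),
    beta2 = c(0.513, -0.252, -0.182, -0.133, 0.146),
    reported_r2 = c(0.354, 0.245, 0.231, 0.223, 0.230),
    reported_tolerance = c(0.561, 0.615, 0.770, 0.990, 0.990)
  )
}

#' Reconstruct the reference regression tables
#'
#' Applies [reconstruct_two_predictor()] to every row of
#' [ptss_reference_models()] and reports the implied quantities next to
#' the printed ones. Printed tolerances can deviate from the implied
#' `1 - r12^2` by a few thousandths because the printed betas are
#' themselves rounded.
#'
#' @return A tibble with the implied `r12`, `r2y`, `r_squared`,
#'   `tolerance` and the reported values.
#' @export
reproduce_reference_tables <- function() {
  ref <- ptss_reference_models()
  rec <- bind_rows(lapply(seq_len(nrow(ref)), function(i) {
    reconstruct_two_predictor(ref$r1y[i], ref$beta1[i], ref$beta2[i])
  }))
  dplyr::bind_cols(
    ref[, c("table", "model", "step2_predictor", "reported_r2",
            "reported_tolerance")],
    rec[, c("r12", "r2y", "r_squared", "tolerance")]
  ) %>%
    mutate(r2_abs_error = abs(.data$r_squared - .data$reported_r2))
}
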