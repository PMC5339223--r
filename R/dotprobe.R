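#' Score a subject's dot-probe attention bias
#'
#' Exclusion rules, applied in order and in a single pass:
#' 1. incorrect responses;
#' 2. response times faster than 150 ms;
#' 3. response times more than 2 SD below or above the subject's mean for
#'    that condition (congruent / incongruent / neutral-neutral), with mean
#'    and SD computed on the survivors of rules 1-2.
#'
#' The bias is mean RT of incongruent trials (probe at the neutral-face
#' location) minus mean RT of congruent trials (probe at the angry-face
#' location): positive = vigilance (faster towards threat), negative =
#' avoidance. Neutral-neutral trials pass through the exclusion
#' bookkeeping but never enter the bias mean. A bias of exactly zero is
#' assigned to the avoidance group by convention.
#'
#' @param trials Tibble of trials with columns `pair_type`
#'   (`"angry-neutral"`/`"neutral-neutral"`), `probe_at_angry_location`
#'   (logical, `NA` for neutral pairs), `rt_ms`, `correct`.
#' @param subject Optional subject identifier carried into the result.
#' @return A one-row tibble: `bias_ms`, `group`, per-congruency used
#'   counts, per-rule excluded counts, and `scorable`.
#' @export
score_bias <- function(trials, subject = NA_character_) {
  stopifnot(all(c("pair_type", "probe_at_angry_location", "rt_ms",
                  "correct") %in% names(trials)))
  if (any(trials$rt_ms <= 0)) abort_invalid("`rt_ms` must be positive.")
  condition <- dplyr::case_when(
    trials$pair_type == "neutral-neutral" ~ "neutral",
    trials$probe_at_angry_location ~ "congruent",
    !trials$probe_at_angry_location ~ "incongruent"
  )
  excl_incorrect <- !trials$correct
  excl_fast <- !excl_incorrect & trials$rt_ms < 150
  survivors <- !excl_incorrect & !excl_fast
  excl_sd <- rep(FALSE, nrow(trials))
  for (cond in unique(condition)) {
    idx <- survivors & condition == cond
    if (sum(idx) >= 2) {
      m <- mean(trials$rt_ms[idx]); s <- sd(trials$rt_ms[idx])
      excl_sd[idx] <- trials$rt_ms[idx] < m - 2 * s |
        trials$rt_ms[idx] > m + 2 * s
    }
  }
  used <- survivors & !excl_sd
  rt_con <- trials$rt_ms[used & condition == "congruent"]
  rt_inc <- trials$rt_ms[used & condition == "incongruent"]
  scorable <- length(rt_con) >= 1 && length(rt_inc) >= 1
  bias <- if (scorable) mean(rt_inc) - mean(rt_con) else NA_real_
  tibble(
    subject = subject,
    bias_ms = bias,
    group = dplyr::case_when(is.na(bias) ~ NA_character_,
                             bias > 0 ~ "vigilance",
                             TRUE ~ "avoidance"),
    n_used_congruent = length(rt_con),
    n_used_incongruent = length(rt_inc),
    n_excluded_incorrect = sum(excl_incorrect),
    n_excluded_fast = sum(excl_fast),
    n_excluded_sd = sum(excl_sd),
    scorable = scorable
  )
}

#' Score every subject of a cohort
#'
#' @param trials Tibble with a `subject` column plus the columns required
#'   by [score_bias()].
#' @return One row per subject (see [score_bias()]).
#' @export
score_bias_cohort <- function(trials) {
  stopifnot("subject" %in% names(trials))
  trials %>%
    dplyr::group_split(.data$subject) %>%
    purrr::map(~ score_bias(.x, subject = .x$subject[1])) %>%
    bind_rows()
}

#' One-sample statistics for a bias group
#'
#' Mean, standard error, one-sample t-test of the bias against zero
#' (df = n - 1) and the one-sample Cohen's d (= t / sqrt(n)).
#'
#' @param scores A scored-bias tibble (from [score_bias_cohort()]).
#' @param group Which group to summarise (`"vigilance"` or `"avoidance"`);
#'   `NULL` uses all scorable subjects.
#' @return A one-row tibble: `group`, `n`, `mean`, `se`, `t`, `df`, `p`, `d`.
#' @export
bias_group_stats <- function(scores, group = NULL) {
  x <- scores$bias_ms[scores$scorable &
                        (if (is.null(group)) TRUE else scores$group %in% group)]
  n <- length(x)
  if (n < 2) abort_invalid("need at least 2 scorable subjects in the group.")
  se <- sd(x) / sqrt(n)
  if (se < 1e-12) {
    t_stat <- NA_real_; p <- NA_real_; d <- NA_real_
  } else {
    t_stat <- mean(x) / se
    p <- 2 * pt(-abs(t_stat), n - 1)
    d <- t_stat / sqrt(n)
  }
  tibble(group = group %||% "all", n = n, mean = mean(x), se = se,
         t = t_stat, df = n - 1, p = p, d = d)
}

#' 2x2 mixed ANOVA: bias group x film period
#'
#' Classical mixed-design analysis with attention-bias group
#' (avoidance/vigilance) as the between-subject factor and film period
#' (low-/high-anger) as the within-subject factor, on the fingerprint
#' window means. Effects are tested with unweighted (type III) cell
#' means, so unequal group sizes do not contaminate the period main
#' effect. Partial eta squared is `SS_effect / (SS_effect + SS_error)`
#' within each effect's error stratum. Simple effects of group within
#' each period are one-way F tests on that period's values (df 1, n - 2).
#'
#' A perfect crossover with no noise drives the interaction F to `Inf`
#' (p = 0); all-equal data return the `NA` path.
#'
#' @param data Tibble with columns `subject`, `group` (two levels),
#'   `low`, `high` (the two period values), complete cases only.
#' @return A `mixed_anova_result` with `$effects` and `$simple_effects`
#'   tibbles.
#' @export
mixed_anova <- function(data) {
  stopifnot(all(c("subject", "group", "low", "high") %in% names(data)))
  data <- dplyr::filter(data, is.finite(.data$low), is.finite(.data$high))
  groups <- sort(unique(data$group))
  if (length(groups) != 2) abort_invalid("exactly two groups required.")
  n_g <- table(factor(data$group, levels = groups))
  if (any(n_g < 2)) abort_invalid("each group needs at least 2 subjects.")
  n <- nrow(data)
  g <- factor(data$group, levels = groups)
  # orthogonal subject-level summaries: mean (between) and difference (within)
  m_i <- (data$low + data$high) / 2
  d_i <- data$high - data$low
  mbar <- tapply(m_i, g, mean)
  dbar <- tapply(d_i, g, mean)
  # between stratum (on subject means, 2 observations each)
  ss_group <- 2 * sum(n_g * (mbar - sum(n_g * mbar) / n)^2)
  ss_err_b <- 2 * sum(tapply(m_i, g, function(v) sum((v - mean(v))^2)))
  df_err <- n - 2
  # within stratum (differences carry period + interaction), orthonormal
  # contrast scale: ss on d are divided by 2
  ss_err_w <- sum(tapply(d_i, g, function(v) sum((v - mean(v))^2))) / 2
  w_unw <- 1 / (1 / n_g[1] + 1 / n_g[2]) # effective n for unweighted means
  ss_period <- 2 * w_unw * mean(dbar)^2      # ((dbar1+dbar2)/2)^2 * 4w / 2
  ss_inter <- w_unw * (dbar[1] - dbar[2])^2 / 2
  f_of <- function(ss_eff, ss_err) {
    if (ss_err < 1e-24) {
      if (ss_eff < 1e-24) NA_real_ else Inf
    } else {
      (ss_eff / 1) / (ss_err / df_err)
    }
  }
  f_vals <- c(group = f_of(ss_group, ss_err_b),
              period = f_of(ss_period, ss_err_w),
              interaction = f_of(ss_inter, ss_err_w))
  ss_eff <- c(ss_group, ss_period, ss_inter)
  ss_err <- c(ss_err_b, ss_err_w, ss_err_w)
  pes <- ifelse(ss_eff + ss_err > 0, ss_eff / (ss_eff + ss_err), NA_real_)
  p_vals <- ifelse(is.na(f_vals), NA_real_,
                   ifelse(is.infinite(f_vals), 0,
                          pf(f_vals, 1, df_err, lower.tail = FALSE)))
  effects <- tibble(
    effect = c("group", "period", "group:period"),
    df1 = 1, df2 = df_err, ss = unname(ss_eff), ss_error = unname(ss_err),
    F = unname(f_vals), p = unname(p_vals), pes = unname(pes)
  )
  simple <- bind_rows(lapply(c(low = "low", high = "high"), function(col) {
    v <- data[[col]]
    vbar <- tapply(v, g, mean)
    ss_e <- sum(vapply(groups, function(gr) {
      sum((v[g == gr] - vbar[gr])^2)
    }, numeric(1)))
    ss_g <- sum(n_g * (vbar - mean(v))^2)
    f <- f_of(ss_g, ss_e)
    tibble(period = col, F = f, df1 = 1, df2 = df_err,
           p = if (is.na(f)) NA_real_ else if (is.infinite(f)) 0 else
             pf(f, 1, df_err, lower.tail = FALSE),
           mean_1 = unname(vbar[1]), mean_2 = unname(vbar[2]))
  }))
  structure(
    list(effects = effects, simple_effects = simple, groups = groups,
         n = n, n_per_group = as.integer(n_g)),
    class = "mixed_anova_result"
  )
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat(sprintf("<mixed 2x2 ANOVA: groups %s (n = %s)>\n",
              paste(x$groups, collapse = " vs "),
              paste(x$n_per_group, collapse = "/")))
  print(x$effects)
  invisible(x)
}

#' @describeIn mixed_anova Tidy effects table.
#' @param x A `mixed_anova_result`.
#' @param ... Unused.
#' @export
tidy.mixed_anova_result <- function(x, ...) x$effects

#' @describeIn mixed_anova One-row summary with the interaction test.
#' @export
glance.mixed_anova_result <- function(x, ...) {
  inter <- x$effects[x$effects$effect == "group:period", ]
  tibble(n = x$n, n_group_1 = x$n_per_group[1], n_group_2 = x$n_per_group[2],
         F_interaction = inter$F, p_interaction = inter$p,
         pes_interaction = inter$pes)
}
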