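test_that("bias arithmetic matches the definition", {
  same <- mk_trials(rep(500, 5), rep(500, 5))
  expect_equal(score_bias(same)$bias_ms, 0)
  expect_equal(score_bias(same)$group, "avoidance") # zero-bias convention
  b <- score_bias(mk_trials(c(480, 500, 520), c(500, 520, 540)))
  expect_equal(b$bias_ms, 20)
  expect_equal(b$group, "vigilance")
  expect_equal(b$n_used_congruent, 3)
})

test_that("exclusion bookkeeping matches a hand trace and the brute-force oracle", {
  trials <- mk_trials(c(100, 480, 500, 520, 900), c(500, 520, 540, 560),
                      neutral = c(500, 510),
                      correct = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                                  FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  b <- score_bias(trials)
  # hand trace: one error (incongruent 500); one fast guess (100 ms);
  # congruent survivors 480/500/520/900: mean 600, sd ~200.3, none beyond
  # 2 SD -> all kept
  expect_equal(b$n_excluded_incorrect, 1)
  expect_equal(b$n_excluded_fast, 1)
  expect_equal(b$bias_ms, mean(c(520, 540, 560)) - mean(c(480, 500, 520, 900)))
  expect_equal(b$bias_ms, brute_bias(trials))
  # randomized fixtures agree with the oracle
  withr::with_seed(51, {
    for (k in 1:10) {
      tr <- generate_dotprobe(n_congruent = 40, n_incongruent = 40,
                              n_neutral_pairs = 12,
                              true_bias_ms = rnorm(1, 0, 25),
                              seed = sample.int(1e6, 1))
      expect_equal(score_bias(tr)$bias_ms, brute_bias(tr))
    }
  })
})

test_that("scoring is order-invariant and ignores neutral trials in the mean", {
  withr::with_seed(52, {
    tr <- generate_dotprobe(true_bias_ms = 10, seed = 7)
    shuffled <- tr[sample.int(nrow(tr)), ]
  })
  expect_equal(score_bias(tr)$bias_ms, score_bias(shuffled)$bias_ms)
  plus_neutral <- dplyr::bind_rows(
    tr, tibble::tibble(pair_type = "neutral-neutral",
                       probe_at_angry_location = NA, rt_ms = 505,
                       correct = TRUE))
  expect_equal(score_bias(plus_neutral)$bias_ms, score_bias(tr)$bias_ms)
})

test_that("an emptied congruency cell flags the subject unscorable", {
  tr <- mk_trials(c(100, 120), c(500, 520), correct = TRUE)
  b <- score_bias(tr)
  expect_false(b$scorable)
  expect_true(is.na(b$bias_ms))
})

test_that("the sign convention stratifies every generated subject", {
  withr::with_seed(53, {
    scores <- dplyr::bind_rows(lapply(1:12, function(i) {
      score_bias(generate_dotprobe(true_bias_ms = rnorm(1, 0, 20),
                                   seed = 1000 + i))
    }))
  })
  expect_true(all((scores$bias_ms > 0) == (scores$group == "vigilance")))
})

test_that("group statistics reproduce the published vigilance summary", {
  # mean 18.7, SE 2.3, n 19 -> t rounds to 8.1; d = t/sqrt(n) from the
  # printed t rounds to 1.86
  t_stat <- 18.7 / 2.3
  expect_equal(round(t_stat, 1), 8.1)
  expect_equal(round(cohens_d_from_t(8.1, 19), 2), 1.86)
  # the same numbers through the scoring interface
  withr::with_seed(54, {
    x <- rnorm(19)
    x <- 18.7 + (x - mean(x)) / sd(x) * (2.3 * sqrt(19))
  })
  scores <- tibble::tibble(bias_ms = x, scorable = TRUE,
                           group = "vigilance")
  gs <- bias_group_stats(scores, "vigilance")
  expect_equal(gs$mean, 18.7)
  expect_equal(gs$se, 2.3)
  expect_equal(round(gs$t, 1), 8.1)
  expect_equal(gs$d, gs$t / sqrt(19))
  # symmetric data about zero
  sym <- tibble::tibble(bias_ms = c(-2, -1, 1, 2), scorable = TRUE,
                        group = "vigilance")
  expect_equal(bias_group_stats(sym, "vigilance")$t, 0)
})

test_that("the 2x2 mixed ANOVA matches a model-comparison oracle on balanced data", {
  withr::with_seed(55, {
    d <- tibble::tibble(
      subject = sprintf("s%02d", 1:32),
      group = rep(c("avoidance", "vigilance"), each = 16),
      low = rnorm(32, rep(c(0, 0.1), each = 16), 0.6),
      high = rnorm(32, rep(c(-0.2, 0.4), each = 16), 0.6)
    )
  })
  res <- mixed_anova(d)
  # oracle: full design-matrix projection via aov with a subject stratum
  long <- tidyr::pivot_longer(d, c("low", "high"), names_to = "period")
  long$period <- factor(long$period, levels = c("low", "high"))
  or <- summary(stats::aov(value ~ group * period + Error(subject),
                           data = long))
  f_between <- or[["Error: subject"]][[1]]["group", "F value"]
  f_within <- or[["Error: Within"]][[1]][c("period", "group:period"),
                                         "F value"]
  expect_equal(res$effects$F, unname(c(f_between, f_within)),
               tolerance = 1e-10)
  expect_equal(res$effects$df2, rep(30, 3))
  # partial eta squared identity on the same fit
  expect_equal(res$effects$pes,
               res$effects$F / (res$effects$F + res$effects$df2),
               tolerance = 1e-12)
  # simple effects: one-way ANOVA per period
  for (p in c("low", "high")) {
    f_simple <- summary(stats::aov(d[[p]] ~ d$group))[[1]]["d$group",
                                                           "F value"]
    expect_equal(res$simple_effects$F[res$simple_effects$period == p],
                 unname(f_simple), tolerance = 1e-10)
  }
})

test_that("a noiseless balanced crossover has an infinite interaction", {
  d <- tibble::tibble(
    subject = sprintf("s%d", 1:8),
    group = rep(c("a", "b"), each = 4),
    low = rep(c(-1, 1), each = 4),
    high = rep(c(1, -1), each = 4)
  )
  res <- mixed_anova(d)
  inter <- res$effects[res$effects$effect == "group:period", ]
  expect_true(is.infinite(inter$F))
  expect_equal(inter$p, 0)
  main <- res$effects[res$effects$effect != "group:period", ]
  expect_true(all(is.na(main$F) | main$F < 1e-10))
  # all-equal data exercise the NA path everywhere
  flat <- mixed_anova(tibble::tibble(subject = sprintf("s%d", 1:6),
                                     group = rep(c("a", "b"), each = 3),
                                     low = 1, high = 1))
  expect_true(all(is.na(flat$effects$F)))
  expect_error(mixed_anova(tibble::tibble(subject = "s1", group = "a",
                                          low = 1, high = 2)),
               class = "angerefp_invalid_argument")
})
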