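test_that("perfect and orthogonal predictors recover textbook identities", {
  withr::with_seed(71, x <- rnorm(40))
  d <- tibble::tibble(y = x, x = x)
  fit <- suppressWarnings(hierarchical_regression(d, "y", list("x")))
  td <- tidy(fit)
  expect_equal(td$beta, 1)
  expect_equal(td$r_squared, 1)
  expect_equal(td$tolerance, 1) # single-predictor step
  # exactly orthogonal centred predictors: step-2 betas are the marginal
  # correlations and the R-squared gains add
  withr::with_seed(72, {
    x1 <- as.numeric(scale(rnorm(60)))
    x2 <- as.numeric(scale(residuals(lm(rnorm(60) ~ x1))))
    y <- rnorm(60)
  })
  Q <- cbind(x1, x2)
  d2 <- tibble::tibble(y = y, x1 = Q[, 1], x2 = Q[, 2])
  fit2 <- hierarchical_regression(d2, "y", list("x1", "x2"))
  td2 <- tidy(fit2)
  g2 <- glance(fit2)
  expect_equal(td2$beta[td2$step == 2],
               c(cor(y, Q[, 1]), cor(y, Q[, 2])), tolerance = 1e-10)
  expect_equal(g2$delta_r_squared[2], cor(y, Q[, 2])^2, tolerance = 1e-10)
  expect_equal(g2$r_squared[2], g2$r_squared[1] + g2$delta_r_squared[2])
})

test_that("an exact-correlation cohort reproduces the reference table values", {
  st <- outcome_structure()
  z <- withr::with_seed(73, {
    MASS::mvrnorm(33, rep(0, 3), st$R, empirical = TRUE) # exact sample cov
  })
  d <- tibble::tibble(state_anger = z[, 1], efp_high = z[, 2], ptss = z[, 3])
  fit <- hierarchical_regression(d, "ptss", list("state_anger", "efp_high"))
  td <- tidy(fit)
  expect_equal(td$beta[td$step == 1], 0.454, tolerance = 1e-10)
  # exact algebra from the reference correlations: R2 = 0.354542
  expect_equal(td$r_squared[td$step == 2][1], 0.354542, tolerance = 1e-4)
  expect_equal(td$r_squared[td$step == 2][1], 0.354, tolerance = 2e-3)
  expect_equal(td$tolerance[td$step == 2][1], 1 - 0.661^2, tolerance = 1e-10)
})

test_that("collinear blocks and constant predictors are rejected by name", {
  withr::with_seed(74, x <- rnorm(30))
  d <- tibble::tibble(y = rnorm(30), a = x, b = 2 * x)
  expect_error(suppressWarnings(hierarchical_regression(d, "y",
                                                        list(c("a", "b")))),
               "collinear")
  d2 <- tibble::tibble(y = rnorm(30), a = 1)
  expect_error(hierarchical_regression(d2, "y", list("a")), "constant")
})

test_that("two-predictor reconstruction inverts the fit to machine precision", {
  # published-value spot checks
  expect_equal(reconstruct_two_predictor(0.454, 0.793, 0.513)$r_squared,
               0.354, tolerance = 2e-3)
  expect_equal(reconstruct_two_predictor(0.454, 0.610, -0.252)$r_squared,
               0.245, tolerance = 2e-3)
  # round trip on simulated fits: feeding the fit's own betas back returns
  # that fit's R2 and tolerance exactly
  withr::with_seed(75, {
    for (k in 1:8) {
      S <- cov2cor(crossprod(matrix(rnorm(9), 3, 3)) + diag(3))
      z <- MASS::mvrnorm(40, rep(0, 3), S)
      d <- tibble::tibble(y = z[, 1], x1 = z[, 2], x2 = z[, 3])
      fit <- hierarchical_regression(d, "y", list("x1", "x2"))
      td <- tidy(fit)
      rec <- reconstruct_two_predictor(td$beta[1], td$beta[2], td$beta[3])
      expect_equal(rec$r_squared, td$r_squared[2], tolerance = 1e-12)
      expect_equal(rec$tolerance, td$tolerance[2], tolerance = 1e-12)
    }
  })
  expect_error(reconstruct_two_predictor(0.9, 0.1, 1e-14),
               class = "angerefp_invalid_argument")
  expect_error(reconstruct_two_predictor(0.9, -0.9, 0.2), "inconsistent")
})

test_that("delta R-squared equals the step difference exactly", {
  withr::with_seed(76, {
    z <- MASS::mvrnorm(50, rep(0, 3), diag(3) * 0.5 + 0.5)
  })
  d <- tibble::tibble(y = z[, 1], x1 = z[, 2], x2 = z[, 3])
  g <- glance(hierarchical_regression(d, "y", list("x1", "x2")))
  expect_identical(g$delta_r_squared[2], g$r_squared[2] - g$r_squared[1])
})

test_that("Cohen's d covers both conventions", {
  withr::with_seed(77, x <- rnorm(19, 18.7, 10))
  expect_equal(cohens_d(x), mean(x) / sd(x))
  expect_equal(cohens_d(x), (mean(x) / (sd(x) / sqrt(19))) / sqrt(19),
               tolerance = 1e-12) # t / sqrt(n) identity
  # hand computation: means 2.5 vs 4.5, pooled SD sqrt(5/3)
  expect_equal(cohens_d(c(1, 2, 3, 4), c(3, 4, 5, 6)), -2 / sqrt(5 / 3))
  expect_equal(cohens_d(c(1, 2), c(1, 2)), 0)
  expect_true(is.na(cohens_d(rep(2, 5))))
})

test_that("the reference tables reconstruct within printed rounding", {
  rec <- reproduce_reference_tables()
  expect_true(all(rec$r2_abs_error[rec$table == 1] < 0.002))
  expect_true(all(abs(rec$tolerance - rec$reported_tolerance) < 0.006))
})
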