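#' Between-subject outcome correlation structure
#'
#' Correlations among state-anger, the high-anger-window fingerprint signal
#' and the 1-year PTSS score, plus the PCL scale parameters. The default
#' correlations are the pair (0.454) reported for state-anger/PTSS together
#' with the values implied by the published two-predictor standardized
#' regression (state-anger/fingerprint -0.661, fingerprint/PTSS -0.011,
#' giving a step-2 R-squared of 0.354 -- a textbook suppression pattern:
#' the fingerprint's marginal validity is near zero yet its beta is large).
#'
#' @param r_sa_efp,r_sa_ptss,r_efp_ptss Pairwise correlations.
#' @param ptss_mean,ptss_sd PCL mean and SD.
#' @param ptss_floor,ptss_ceiling PCL bounds (17-item checklist: 17-85).
#' @param sa_mean,sa_sd State-anger location and scale.
#' @param n_subjects Cohort size.
#' @return An `outcome_structure` object.
#' @export
outcome_structure <- function(r_sa_efp = -0.661, r_sa_ptss = 0.454,
                              r_efp_ptss = -0.011,
                              ptss_mean = 27.6, ptss_sd = 9.4,
                              ptss_floor = 17, ptss_ceiling = 85,
                              sa_mean = 30, sa_sd = 8,
                              n_subjects = 33) {
  R <- matrix(c(1, r_sa_efp, r_sa_ptss,
                r_sa_efp, 1, r_efp_ptss,
                r_sa_ptss, r_efp_ptss, 1), 3, 3,
              dimnames = rep(list(c("state_anger", "efp_high", "ptss")), 2))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort_invalid(sprintf(
      "correlation matrix is not positive semidefinite (eigenvalue %.4g).",
      min(ev)))
  }
  structure(
    list(R = R, r_sa_efp = r_sa_efp, r_sa_ptss = r_sa_ptss,
         r_efp_ptss = r_efp_ptss, ptss_mean = ptss_mean, ptss_sd = ptss_sd,
         ptss_floor = ptss_floor, ptss_ceiling = ptss_ceiling,
         sa_mean = sa_mean, sa_sd = sa_sd, n_subjects = n_subjects),
    class = "outcome_structure"
  )
}

#' Draw per-subject outcomes
#'
#' A trivariate Gaussian draw with the requested correlation structure.
#' State-anger is affinely scaled to the STAXI-like location/scale, the
#' fingerprint window mean is left as a z-score, and PTSS is mapped to the
#' PCL mean/SD, rounded to the nearest integer and then clamped to the
#' scale bounds. `ptss_raw` keeps the unclamped continuous value so that
#' the Gaussian correlation structure remains checkable; `ptss_clamped`
#' flags subjects the clamp touched.
#'
#' @param structure An [outcome_structure()].
#' @param seed Integer seed.
#' @param n Number of subjects; defaults to `structure$n_subjects`.
#' @return A tibble with one row per subject.
#' @export
generate_outcomes <- function(structure = outcome_structure(), seed = 1,
                              n = NULL) {
  stopifnot(inherits(structure, "outcome_structure"))
  n <- n %||% structure$n_subjects
  z <- withr::with_seed(seed, MASS::mvrnorm(n, mu = rep(0, 3),
                                            Sigma = structure$R))
  if (n == 1) z <- matrix(z, 1)
  ptss_raw <- structure$ptss_mean + structure$ptss_sd * z[, 3]
  ptss <- pmin(pmax(round(ptss_raw), structure$ptss_floor),
               structure$ptss_ceiling)
  tibble(
    subject = sprintf("sub-%03d", seq_len(n)),
    state_anger = structure$sa_mean + structure$sa_sd * z[, 1],
    efp_high = z[, 2],
    ptss_raw = ptss_raw,
    ptss = as.numeric(ptss),
    ptss_clamped = round(ptss_raw) < structure$ptss_floor |
      round(ptss_raw) > structure$ptss_ceiling
  )
}
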