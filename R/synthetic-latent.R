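#' Latent anger-intensity profile
#'
#' Parameters of the shared latent driver that stands in for the film-evoked
#' anger dynamic: a smooth trapezoidal bump on a constant baseline. The bump
#' rises linearly from `bump_onset_s` to `bump_peak_s`, stays at
#' `bump_amplitude` until `bump_offset_s`, and falls back over the same ramp
#' duration. Defaults place the plateau inside the 189-288 s high-anger
#' period of a 321 s recording.
#'
#' @param duration_s Recording duration in seconds.
#' @param rate_hz Sampling rate of the latent trace.
#' @param baseline Baseline level (arbitrary units).
#' @param bump_onset_s Start of the rising ramp (s).
#' @param bump_peak_s Start of the plateau (s).
#' @param bump_offset_s End of the plateau (s).
#' @param bump_amplitude Plateau height above baseline (arbitrary units).
#' @return A `latent_profile` object.
#' @export
latent_profile <- function(duration_s = 321, rate_hz = 10, baseline = 0,
                           bump_onset_s = 185, bump_peak_s = 205,
                           bump_offset_s = 285, bump_amplitude = 1) {
  vals <- c(duration_s, rate_hz, baseline, bump_onset_s, bump_peak_s,
            bump_offset_s, bump_amplitude)
  if (!all(is.finite(vals))) abort_invalid("profile values must be finite.")
  if (duration_s <= 0 || rate_hz <= 0) {
    abort_invalid("`duration_s` and `rate_hz` must be positive.")
  }
  if (!(0 <= bump_onset_s && bump_onset_s <= bump_peak_s &&
        bump_peak_s <= bump_offset_s && bump_offset_s <= duration_s)) {
    abort_invalid("need 0 <= bump_onset_s <= bump_peak_s <= bump_offset_s <= duration_s.")
  }
  structure(
    list(
      duration_s = duration_s, rate_hz = rate_hz, baseline = baseline,
      bump_onset_s = bump_onset_s, bump_peak_s = bump_peak_s,
      bump_offset_s = bump_offset_s, bump_amplitude = bump_amplitude
    ),
    class = "latent_profile"
  )
}

latent_trapezoid <- function(profile, t) {
  ramp <- profile$bump_peak_s - profile$bump_onset_s
  up <- if (ramp > 0) {
    pmin(pmax((t - profile$bump_onset_s) / ramp, 0), 1)
  } else {
    as.numeric(t >= profile$bump_onset_s)
  }
  down <- if (ramp > 0) {
    pmin(pmax((profile$bump_offset_s + ramp - t) / ramp, 0), 1)
  } else {
    as.numeric(t < profile$bump_offset_s)
  }
  profile$baseline + profile$bump_amplitude * pmin(up, down)
}

#' Generate the latent anger-intensity trace
#'
#' Deterministic given `seed`: the trapezoid of the profile plus AR(1) noise
#' (autocorrelation 0.9) whose stationary standard deviation is 10% of the
#' bump amplitude, emulating slow idiosyncratic drift of the evoked state.
#' With `bump_amplitude = 0` the noise vanishes too and the trace is exactly
#' the baseline.
#'
#' @param profile A [latent_profile()].
#' @param seed Integer seed; identical seeds give bit-identical traces.
#' @return A sampled series tibble (`time_s`, `value`).
#' @export
generate_latent <- function(profile = latent_profile(), seed = 1) {
  stopifnot(inherits(profile, "latent_profile"))
  n <- round(profile$duration_s * profile$rate_hz)
  if (n < 1) abort_invalid("profile too short for its sampling rate.")
  t <- (seq_len(n) - 1) / profile$rate_hz
  shape <- latent_trapezoid(profile, t)
  noise <- withr::with_seed(seed, {
    ar1_noise(n, phi = 0.9, sd = 0.1 * abs(profile$bump_amplitude))
  })
  sampled_series(shape + noise, rate_hz = profile$rate_hz, start_s = 0)
}

ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- rnorm(n, 0, innov_sd)
  as.numeric(stats::filter(e, phi, method = "recursive", init = rnorm(1, 0, sd)))
}

# Linear interpolation lookup of a sampled series at arbitrary times
# (constant extrapolation at the edges).
series_at <- function(series, t) {
  stats::approx(series$time_s, series$value, xout = t, rule = 2)$y
}
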