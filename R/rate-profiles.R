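#' Time-varying instantaneous firing-rate profiles
#'
#' A rate profile describes the instantaneous firing rate of a Purkinje cell
#' as a function of time. Two kinds are supported: a constant rate, and a
#' sinusoid oscillating around a baseline, mimicking the modulation of simple
#' spike rates across a locomotor (step) cycle. The profile is shared by all
#' cells of an ensemble: at every timestep the spike probability is the same
#' for every cell, but spike outcomes are independent.
#'
#' @param rate_hz constant firing rate in Hz (must be >= 0).
#' @return An object of class `rate_profile`.
#' @examples
#' constant_rate(200)
#' sinusoid_rate(amplitude_hz = 100, baseline_hz = 150, wavelength_ms = 200)
#' @export
constant_rate <- function(rate_hz) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz < 0) {
    stop("`rate_hz` must be a single non-negative number")
  }
  structure(list(kind = "constant", rate_hz = rate_hz), class = "rate_profile")
}

#' @rdname constant_rate
#' @param amplitude_hz amplitude `a` of the oscillation either side of the
#'   baseline, in Hz.
#' @param baseline_hz baseline (mean) rate `b` in Hz; the instantaneous rate
#'   oscillates in `[b - a, b + a]`, so `b - a` must be >= 0.
#' @param wavelength_ms period of one cycle in ms (> 0).
#' @param phase0 phase at t = 0 in radians. The default 0 starts the cycle at
#'   the baseline on the rising limb.
#' @export
sinusoid_rate <- function(amplitude_hz, baseline_hz, wavelength_ms,
                          phase0 = 0) {
  if (amplitude_hz < 0) stop("`amplitude_hz` must be non-negative")
  if (baseline_hz - amplitude_hz < 0) {
    stop("instantaneous rate would go negative: require baseline_hz >= amplitude_hz")
  }
  if (wavelength_ms <= 0) stop("`wavelength_ms` must be positive")
  structure(
    list(kind = "sinusoid", amplitude_hz = amplitude_hz,
         baseline_hz = baseline_hz, wavelength_ms = wavelength_ms,
         phase0 = phase0),
    class = "rate_profile"
  )
}

#' @export
print.rate_profile <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("<rate_profile> constant %g Hz\n", x$rate_hz))
  } else {
    cat(sprintf(
      "<rate_profile> sinusoid %g +/- %g Hz, wavelength %g ms, phase0 %g rad\n",
      x$baseline_hz, x$amplitude_hz, x$wavelength_ms, x$phase0))
  }
  invisible(x)
}

#' Evaluate a rate profile at given times
#'
#' For a sinusoid the instantaneous rate is
#' `b + a * sin(2 * pi * t / wavelength + phase0)`.
#'
#' @param profile a [constant_rate()] or [sinusoid_rate()] object.
#' @param t time(s) in ms, all >= 0. Vectorized.
#' @return Instantaneous rate(s) in Hz.
#' @export
evaluate_rate <- function(profile, t) {
  stopifnot(inherits(profile, "rate_profile"))
  if (any(t < 0)) stop("`t` must be non-negative")
  if (profile$kind == "constant") {
    rep(profile$rate_hz, length(t))
  } else {
    profile$baseline_hz +
      profile$amplitude_hz *
        sin(2 * pi * t / profile$wavelength_ms + profile$phase0)
  }
}

#' Convert an instantaneous rate to a per-timestep spike probability
#'
#' A rate of N Hz on a timestep of `dt` ms gives a spike probability of
#' `N * dt / 1000` per timestep; at the default 0.05 ms grid this is
#' N / 20,000. The result is clamped at 1 (it only reaches the clamp for
#' rates >= 1000/dt Hz, far above the physiological range).
#'
#' @param rate rate(s) in Hz, >= 0. Vectorized.
#' @param dt timestep in ms (> 0).
#' @return Spike probability per timestep, in `[0, 1]`.
#' @examples
#' rate_to_probability(200, 0.05) # 0.01
#' @export
rate_to_probability <- function(rate, dt) {
  if (any(rate < 0)) stop("`rate` must be non-negative")
  if (dt <= 0) stop("`dt` must be positive")
  pmin(rate * dt / 1000, 1)
}

#' Map the wavelength-adjustment factor z to a wavelength in ms
#'
#' Curves of the form `a * sin(z * x / pi) + b`, with `x` time in ms, have
#' period `2 * pi^2 / z` ms. These helpers convert between the adjustment
#' factor and the wavelength.
#'
#' @param z wavelength-adjustment factor (> 0).
#' @return Wavelength in ms (or `z` for the inverse mapping).
#' @export
wavelength_from_z <- function(z) {
  if (any(z <= 0)) stop("`z` must be positive")
  2 * pi^2 / z
}

#' @rdname wavelength_from_z
#' @param wavelength_ms wavelength in ms (> 0).
#' @export
z_from_wavelength <- function(wavelength_ms) {
  if (any(wavelength_ms <= 0)) stop("`wavelength_ms` must be positive")
  2 * pi^2 / wavelength_ms
}
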