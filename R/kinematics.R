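#' Minimum-jerk reach velocity profile
#'
#' Velocity toward the target for a straight point-to-point reach under the
#' minimum-jerk model: `v(t) = 30 A/T * tau^2 (1 - tau)^2`, `tau = t/T`.
#' The profile is bell-shaped, zero at both ends, peaks at mid-movement
#' with `v_peak = 1.875 A / T`, and integrates to the movement amplitude.
#' A trace whose peak velocity falls outside the 0.2--0.55 m/s acceptance
#' window used for reach validation is flagged invalid (it would be
#' excluded from analysis), not rejected.
#'
#' @param amplitude Movement distance in metres (target separation 0.10 m).
#' @param duration Movement time in seconds.
#' @param dt Sampling interval in seconds (1 kHz default).
#' @return A `movement_trace`: list with `t`, `vy` (m/s), `peak_velocity`,
#'   `peak_index`, `duration`, `amplitude`, `dt` and logical `valid`.
#' @examples
#' tr <- minimum_jerk_velocity(0.10, 0.5)
#' tr$peak_velocity  # 1.875 * 0.10 / 0.5 = 0.375 m/s
#' @export
minimum_jerk_velocity <- function(amplitude = 0.10, duration = 0.5,
                                  dt = 1e-3) {
  stopifnot(amplitude > 0, duration > 0, dt > 0)
  t <- seq(0, duration, by = dt)
  tau <- t / duration
  vy <- 30 * amplitude / duration * tau^2 * (1 - tau)^2
  peak_index <- which.max(vy)[1]
  pv <- 1.875 * amplitude / duration  # analytic peak, grid-independent
  structure(list(t = t, vy = vy, peak_velocity = pv,
                 peak_index = peak_index, duration = duration,
                 amplitude = amplitude, dt = dt,
                 valid = pv >= 0.2 && pv <= 0.55),
            class = "movement_trace")
}

#' @export
print.movement_trace <- function(x, ...) {
  cat(sprintf(
    "<movement_trace> %.0f ms, amplitude %.3f m, peak velocity %.3f m/s%s\n",
    x$duration * 1000, x$amplitude, x$peak_velocity,
    if (x$valid) "" else " [INVALID: outside 0.2-0.55 m/s]"))
  invisible(x)
}

#' Force-field specification
#'
#' The velocity-dependent curl field applies a lateral force proportional
#' to reach velocity, `F_lateral = c * k * vy`, with viscosity
#' `k = 15 Ns/m`. The direction coefficient `c` sets which side the field
#' pushes toward (`+1`: rightward on the analysed 270-degree reach).
#'
#' @param k Field viscosity in Ns/m.
#' @param c Direction sign, -1 or +1.
#' @return A `force_field_spec` list.
#' @export
force_field_spec <- function(k = 15, c = 1) {
  stopifnot(k > 0, c %in% c(-1, 1))
  structure(list(k = k, c = c), class = "force_field_spec")
}

#' Ideal lateral force of the curl field
#'
#' The perturbing force the field exerts during a reach, pointwise
#' proportional to velocity: `c * k * vy`. The ideal *compensatory* force a
#' fully adapted subject must produce is its negative; the adaptation
#' coefficient regression handles that sign flip internally.
#'
#' @param trace A [minimum_jerk_velocity()] trace (or any list with `vy`).
#' @param ff A [force_field_spec()].
#' @return Numeric force time series (N), same length as `trace$vy`.
#' @export
ideal_force_profile <- function(trace, ff = force_field_spec()) {
  stopifnot(inherits(ff, "force_field_spec"))
  ff$c * ff$k * trace$vy
}

#' Applied noise waveform
#'
#' The externally applied motor noise: a sinusoid `m sin(2 pi f t)` at the
#' essential-tremor-band frequency `f = 10` Hz with amplitude `m` of 0, 3
#' or 7 N depending on group.
#'
#' @param m Amplitude in newtons.
#' @param t Time grid in seconds (sorted).
#' @param f Frequency in Hz.
#' @return Numeric force series (N) on `t`.
#' @examples
#' max(abs(noise_waveform(7, seq(0, 1, by = 1e-3))))  # 7
#' @export
noise_waveform <- function(m, t, f = 10) {
  stopifnot(m >= 0, f > 0, !is.unsorted(t))
  m * sin(2 * pi * f * t)
}

#' Dominant frequency by periodogram
#'
#' Frequency of the largest raw-periodogram ordinate of a uniformly
#' sampled series (zero frequency excluded).
#'
#' @param x Numeric series.
#' @param dt Sampling interval in seconds.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(x, dt = 1e-3) {
  n <- length(x)
  stopifnot(n > 3, dt > 0)
  spec <- Mod(stats::fft(x - mean(x)))^2
  half <- 2:(floor(n / 2) + 1)           # positive frequencies only
  freq <- (half - 1) / (n * dt)
  freq[which.max(spec[half])]
}
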