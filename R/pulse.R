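# Gyromagnetic ratio of 1H in rad s^-1 uT^-1 (2*pi*42.577 MHz/T * 1e-6).
GAMMA_1H <- 267.522

# Stored shape factors for named pulse presets. The "gaussian" preset is a
# truncated-Gaussian excitation of the kind used for bSSFP cardiac imaging;
# its factors are measured properties of the vendor waveform, not derivable
# from an idealised analytic Gaussian.
PULSE_PRESETS <- list(
  block    = list(delta1 = 1.00, delta2 = 1.00),
  gaussian = list(delta1 = 0.53, delta2 = 0.40)
)

#' RF pulse model
#'
#' An RF pulse is represented either by a sampled nonnegative amplitude
#' envelope (peak-normalized to 1) or by a named preset carrying stored shape
#' factors. Two dimensionless factors characterise a pulse relative to a block
#' (rectangular) pulse of the same duration and peak amplitude: `delta1`, the
#' relative duration (integral of the envelope over peak x duration), and
#' `delta2`, the relative energy (integral of the squared envelope). For any
#' valid envelope `delta1^2 <= delta2 <= delta1`.
#'
#' @param waveform Optional numeric vector: sampled amplitude envelope,
#'   nonnegative, uniformly sampled over the pulse duration. It is
#'   peak-normalized internally. At least 8 samples are required.
#' @param preset Optional preset name, one of `"block"`, `"gaussian"`.
#' @param tau Pulse duration in ms. Must be positive.
#' @return An object of class `rf_pulse` with fields `tau`, `delta1`,
#'   `delta2`, and (for sampled pulses) `waveform`.
#' @examples
#' p <- rf_pulse(preset = "gaussian", tau = 1.2)
#' p$delta1  # 0.53
#' hs <- rf_pulse(waveform = sin(pi * seq(0, 1, length.out = 513)), tau = 1)
#' hs$delta1 # ~ 2/pi
#' @export
rf_pulse <- function(waveform = NULL, preset = NULL, tau = 1.0) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("invalid-pulse: tau must be a positive scalar (ms)")
  if (is.null(waveform) == is.null(preset))
    stop("invalid-pulse: give exactly one of waveform or preset")
  if (!is.null(preset)) {
    if (!preset %in% names(PULSE_PRESETS))
      stop(sprintf("invalid-pulse: unknown preset '%s'", preset))
    fac <- PULSE_PRESETS[[preset]]
    out <- list(preset = preset, waveform = NULL, tau = tau,
                delta1 = fac$delta1, delta2 = fac$delta2)
  } else {
    if (!is.numeric(waveform) || length(waveform) < 8L)
      stop("invalid-pulse: waveform needs >= 8 samples")
    if (any(!is.finite(waveform)) || any(waveform < 0))
      stop("invalid-pulse: waveform must be finite and nonnegative")
    pk <- max(waveform)
    if (pk <= 0) stop("invalid-pulse: zero peak amplitude")
    waveform <- waveform / pk
    fac <- shape_factors_sampled(waveform)
    out <- list(preset = NULL, waveform = waveform, tau = tau,
                delta1 = fac[[1L]], delta2 = fac[[2L]])
  }
  structure(out, class = "rf_pulse")
}

# Trapezoidal mean of f over a unit interval given uniform samples.
trapz_mean <- function(y) {
  n <- length(y)
  (sum(y) - 0.5 * (y[1L] + y[n])) / (n - 1L)
}

shape_factors_sampled <- function(waveform) {
  c(delta1 = trapz_mean(waveform), delta2 = trapz_mean(waveform^2))
}

#' Pulse shape factors
#'
#' Returns the relative duration `delta1` and relative energy `delta2` of a
#' pulse: the duration/energy of the pulse divided by that of a block pulse
#' with the same peak amplitude and total duration. Sampled waveforms are
#' integrated by trapezoidal quadrature on the uniform sample grid; presets
#' return their stored values.
#'
#' @param pulse An [rf_pulse()].
#' @return Named numeric vector `c(delta1 = ..., delta2 = ...)`.
#' @export
shape_factors <- function(pulse) {
  stopifnot(inherits(pulse, "rf_pulse"))
  c(delta1 = pulse$delta1, delta2 = pulse$delta2)
}

#' Peak pulse amplitude for a target flip angle
#'
#' The on-resonance flip angle produced at unit transmit sensitivity is
#' `theta0 = delta1 * p_max * tau * gamma` (tau in seconds). This inverts
#' that relation to give the peak amplitude `p_max` (uT) that achieves a
#' requested flip angle.
#'
#' @param theta0 Target flip angle in radians, `>= 0`.
#' @param pulse An [rf_pulse()]; supplies `delta1` and `tau` (ms).
#' @param gamma Gyromagnetic ratio in rad s^-1 uT^-1; default 267.522 (1H).
#' @return Peak amplitude in uT.
#' @export
peak_amp_for_flip <- function(theta0, pulse, gamma = GAMMA_1H) {
  stopifnot(inherits(pulse, "rf_pulse"))
  if (!is.numeric(theta0) || length(theta0) != 1L || !is.finite(theta0) ||
      theta0 < 0)
    stop("domain error: theta0 must be a nonnegative scalar (rad)")
  if (gamma <= 0) stop("domain error: gamma must be positive")
  tau_s <- pulse$tau * 1e-3
  theta0 / (pulse$delta1 * gamma * tau_s)
}

#' Sequence timing
#'
#' Container for the repetition time TR, the spatial-encoding time, and the
#' amplifier gating duty-cycle limit `delta0` (the maximum fraction of TR for
#' which the amplifier may be unblanked, irrespective of power).
#'
#' @param tr Repetition time (ms).
#' @param t_enc Spatial-encoding time (ms): gradient time that must fit in TR
#'   alongside the RF pulse.
#' @param delta0 Gating duty-cycle limit in (0, 1]; default 0.5.
#' @return Object of class `sequence_timing`.
#' @export
sequence_timing <- function(tr, t_enc = 1.7, delta0 = 0.5) {
  if (!is.numeric(delta0) || delta0 <= 0 || delta0 > 1)
    stop("config error: delta0 must lie in (0, 1]")
  if (tr <= 0 || t_enc <= 0) stop("timing error: tr and t_enc must be positive")
  structure(list(tr = tr, t_enc = t_enc, delta0 = delta0),
            class = "sequence_timing")
}

#' Sequence power duty cycle
#'
#' Fraction of time-averaged RF energy relative to continuous block
#' transmission: `Delta = delta2 * tau / TR`.
#'
#' @param pulse An [rf_pulse()].
#' @param timing A [sequence_timing()] (or a TR value in ms).
#' @return Dimensionless duty cycle in (0, 1].
#' @export
duty_cycle <- function(pulse, timing) {
  stopifnot(inherits(pulse, "rf_pulse"))
  tr <- if (inherits(timing, "sequence_timing")) timing$tr else timing
  if (tr < pulse$tau) stop("timing error: tr < tau")
  pulse$delta2 * pulse$tau / tr
}

#' Minimum achievable TR for a pulse duration
#'
#' The TR floor irrespective of power or SAR: the RF pulse and the spatial
#' encoding gradients must both fit into TR, and the amplifier gating duty
#' cycle caps `tau / TR` at `delta0`. Hence
#' `TR_min = max(tau + t_enc, tau / delta0)`, piecewise linear in `tau` with
#' a breakpoint at `tau = t_enc * delta0 / (1 - delta0)`.
#'
#' @param tau Pulse duration (ms), positive.
#' @param t_enc Spatial-encoding time (ms), positive.
#' @param delta0 Gating duty-cycle limit in (0, 1].
#' @return Minimum TR in ms.
#' @export
min_tr <- function(tau, t_enc = 1.7, delta0 = 0.5) {
  if (!is.numeric(delta0) || length(delta0) != 1L || delta0 <= 0 || delta0 > 1)
    stop("config error: delta0 must lie in (0, 1]")
  if (any(tau <= 0) || t_enc <= 0)
    stop("timing error: tau and t_enc must be positive")
  pmax(tau + t_enc, tau / delta0)
}

#' Per-channel peak and average forward power
#'
#' A channel driven with shim amplitude `|w_j|` and peak pulse amplitude
#' `p_max` requires peak power `A * (|w_j| * p_max)^2`, where `A` (W/uT^2) is
#' the gain of the RF chain; the average power is the peak power times the
#' sequence duty cycle.
#'
#' @param wj_amplitude Shim amplitude(s) `|w_j|`, nonnegative.
#' @param p_max Peak pulse amplitude (uT).
#' @param A RF chain gain (W/uT^2), positive.
#' @param Delta Sequence power duty cycle (dimensionless).
#' @return List with numeric `peak` and `average` (W), same length as
#'   `wj_amplitude`.
#' @export
per_channel_power <- function(wj_amplitude, p_max, A, Delta) {
  if (any(wj_amplitude < 0)) stop("domain error: amplitudes must be >= 0")
  if (A <= 0) stop("domain error: A must be positive")
  peak <- A * (wj_amplitude * p_max)^2
  list(peak = peak, average = peak * Delta)
}

#' @export
print.rf_pulse <- function(x, ...) {
  nm <- if (is.null(x$preset)) sprintf("sampled (%d pts)", length(x$waveform))
        else x$preset
  cat(sprintf("<rf_pulse> %s: tau = %g ms, delta1 = %.4g, delta2 = %.4g\n",
              nm, x$tau, x$delta1, x$delta2))
  invisible(x)
}
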