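#' Force trace container
#'
#' A uniformly sampled force (or encoded sensor-voltage) time series for one
#' trial segment, as read from a force-sensing resistor (FSR) channel.
#'
#' @param samples Numeric vector of samples, ordered in time.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param t0_ms Time of the first sample relative to trial start (ms).
#' @param channel `"force_N"` or `"voltage"`.
#' @param participant_id,trial_index,part Optional provenance metadata;
#'   `part` is `"prime"` or `"probe"`.
#'
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(samples, sample_rate_hz, t0_ms = 0,
                        channel = c("force_N", "voltage"),
                        participant_id = NA_integer_,
                        trial_index = NA_integer_,
                        part = NA_character_) {
  channel <- match.arg(channel)
  if (!is.numeric(samples) || length(samples) == 0L || any(!is.finite(samples)))
    stop("samples must be a non-empty finite numeric vector", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive", call. = FALSE)
  if (channel == "force_N" && any(samples < 0))
    stop("force samples must be non-negative", call. = FALSE)
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = sample_rate_hz,
         t0_ms = t0_ms,
         channel = channel,
         participant_id = participant_id,
         trial_index = trial_index,
         part = part),
    class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples @ %g Hz, channel %s, t0 = %g ms\n",
              length(x$samples), x$sample_rate_hz, x$channel, x$t0_ms))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$samples), max(x$samples)))
  invisible(x)
}

#' Sample times of a force trace
#'
#' @param trace A [force_trace()].
#' @return Numeric vector of sample times in ms (trial clock).
#' @export
trace_times_ms <- function(trace) {
  trace$t0_ms + (seq_along(trace$samples) - 1L) * 1000 / trace$sample_rate_hz
}

#' Synthesize an idealized pinch pulse
#'
#' Generates the raised-sine-squared pulse used as the canonical pinch shape:
#' `F(t) = peak_N * sin^2(pi * t / duration_ms)` for `t` in
#' `[0, duration_ms]`, zero outside. The shape has closed-form peak (at
#' `duration_ms / 2`), integral (`peak_N * duration_ms / 2`) and threshold
#' crossing times (`(D / pi) * asin(sqrt(thr / P))` and its mirror), which
#' makes detection and feature extraction analytically checkable.
#'
#' @param peak_N Peak force (N), > 0.
#' @param duration_ms Pulse duration (ms), > 0.
#' @param sample_rate_hz Sampling rate (Hz), > 0.
#' @param t0_ms Time of pulse onset on the trial clock (ms); the returned
#'   trace starts `pad_ms` before it.
#' @param pad_ms Zero padding before and after the pulse (ms).
#' @return A [force_trace()] on the `force_N` channel.
#' @examples
#' p <- make_pulse(4, 200, 1000)
#' max(p$samples)  # 4 N at t = 100 ms
#' @export
make_pulse <- function(peak_N, duration_ms, sample_rate_hz,
                       t0_ms = 0, pad_ms = 50) {
  if (peak_N <= 0 || duration_ms <= 0 || sample_rate_hz <= 0 || pad_ms < 0)
    stop("peak_N, duration_ms and sample_rate_hz must be positive", call. = FALSE)
  dt_ms <- 1000 / sample_rate_hz
  t <- seq(-pad_ms, duration_ms + pad_ms, by = dt_ms)
  f <- ifelse(t >= 0 & t <= duration_ms,
              peak_N * sin(pi * t / duration_ms)^2, 0)
  force_trace(f, sample_rate_hz, t0_ms = t0_ms - pad_ms, channel = "force_N")
}

#' Convert an encoded FSR voltage trace to force
#'
#' The FSR voltage reading is calibrated to force with an exponential
#' transform: `F = a * exp(b * V)`. Metadata are preserved.
#'
#' @param trace A [force_trace()] on the `voltage` channel.
#' @param a Gain (N), > 0: the force at zero volts.
#' @param b Exponent (per volt), non-zero.
#' @return The trace on the `force_N` channel.
#' @seealso [encode_voltage()] for the inverse.
#' @export
voltage_to_force <- function(trace, a = 0.05, b = 1.5) {
  stopifnot(inherits(trace, "force_trace"))
  if (trace$channel != "voltage")
    stop("voltage_to_force() expects a voltage-channel trace", call. = FALSE)
  if (a <= 0 || b == 0) stop("require a > 0 and b != 0", call. = FALSE)
  out <- trace
  out$samples <- a * exp(b * trace$samples)
  out$channel <- "force_N"
  out
}

#' Encode a force trace as FSR voltage
#'
#' Exact inverse of [voltage_to_force()] above the representable floor:
#' `V = log(max(F, floor_N) / a) / b`. Samples below `floor_N` clip to the
#' baseline voltage `log(floor_N / a) / b` (an FSR at rest still reads a
#' finite voltage).
#'
#' @param trace A [force_trace()] on the `force_N` channel.
#' @param a,b Calibration constants as in [voltage_to_force()].
#' @param floor_N Smallest representable force (N), > 0.
#' @return The trace on the `voltage` channel.
#' @export
encode_voltage <- function(trace, a = 0.05, b = 1.5, floor_N = 1e-6) {
  stopifnot(inherits(trace, "force_trace"))
  if (trace$channel != "force_N")
    stop("encode_voltage() expects a force-channel trace", call. = FALSE)
  if (a <= 0 || b == 0 || floor_N <= 0)
    stop("require a > 0, b != 0, floor_N > 0", call. = FALSE)
  if (any(!is.finite(trace$samples)))
    stop("non-finite force samples", call. = FALSE)
  out <- trace
  out$samples <- log(pmax(trace$samples, floor_N) / a) / b
  out$channel <- "voltage"
  out
}
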