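#' Command waveforms for the recording protocols
#'
#' A `command_waveform` is a uniformly sampled command signal for one
#' protocol sweep: a voltage command in voltage clamp (mV) or an injected
#' current command in current clamp (pA). All waveform constructors prepend a
#' baseline hold so that resting / leak windows exist before the stimulus.
#'
#' Unit system throughout the package: ms, mV, pA, nS, pF. With these units
#' pA/nS = mV and pA/pF = mV/ms, so the membrane equations carry no unit
#' conversion coefficients.
#'
#' @param mode `"voltage_clamp"` or `"current_clamp"`.
#' @param dt Sample interval in ms (> 0).
#' @param values Numeric vector of command samples (mV or pA per `mode`).
#' @param baseline_n Number of leading baseline-hold samples.
#' @param epochs Optional named list of index ranges (`c(first, last)`)
#'   marking protocol segments, e.g. `ramp`, `step`.
#' @return An object of class `command_waveform`.
#' @export
command_waveform <- function(mode, dt, values, baseline_n = 0L, epochs = list()) {
  mode <- match.arg(mode, c("voltage_clamp", "current_clamp"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop_invalid("dt must be a single positive number (ms)")
  if (!is.numeric(values) || length(values) < 1L || !all(is.finite(values)))
    stop_invalid("command values must be finite and non-empty")
  structure(
    list(mode = mode, dt = dt, values = as.numeric(values),
         baseline_n = as.integer(baseline_n), epochs = epochs),
    class = "command_waveform"
  )
}

#' @export
print.command_waveform <- function(x, ...) {
  unit <- if (x$mode == "voltage_clamp") "mV" else "pA"
  cat(sprintf("<command_waveform> %s, %d samples @ dt = %g ms (%.3f s), range [%g, %g] %s\n",
              x$mode, length(x$values), x$dt,
              length(x$values) * x$dt / 1000,
              min(x$values), max(x$values), unit))
  invisible(x)
}

#' @export
length.command_waveform <- function(x) length(x$values)

#' Sample times of a waveform or trace
#'
#' @param x A `command_waveform` or `trace`.
#' @return Numeric vector of sample times in ms, starting at 0.
#' @export
wave_times <- function(x) (seq_along(x$values) - 1) * x$dt

#' @export
as.data.frame.command_waveform <- function(x, ...) {
  data.frame(time_ms = wave_times(x), command = x$values)
}

#' Slow voltage bi-ramp command
#'
#' Symmetric triangular voltage command: baseline hold at `v_start`, linear
#' rise to `v_peak` at `rate`, then linear return to `v_start` at the same
#' rate. The standard PIC protocol runs from -80 mV to +10 mV at 20 mV/s,
#' i.e. 9 s up-and-down.
#'
#' @param v_start Start/return voltage (mV).
#' @param v_peak Peak voltage (mV); must exceed `v_start`.
#' @param rate Ramp speed in mV/s (> 0).
#' @param dt Sample interval (ms).
#' @param baseline_ms Pre-ramp hold duration at `v_start` (ms).
#' @return A voltage-clamp `command_waveform` with a `ramp` epoch and a
#'   `ramp_peak` index attribute in `epochs`.
#' @export
make_voltage_biramp <- function(v_start = -80, v_peak = 10, rate = 20,
                                dt = 0.1, baseline_ms = 500) {
  if (!is.finite(rate) || rate <= 0) stop_invalid("rate must be positive (mV/s)")
  if (!is.finite(dt) || dt <= 0) stop_invalid("dt must be positive (ms)")
  if (!(v_peak > v_start)) stop_invalid("v_peak must exceed v_start")
  r <- rate / 1000                         # mV/ms
  t_asc <- (v_peak - v_start) / r          # ms
  n_base <- round(baseline_ms / dt)
  n_ramp <- round(2 * t_asc / dt) + 1L
  t_ramp <- (seq_len(n_ramp) - 1) * dt
  ramp <- v_start + r * pmin(t_ramp, 2 * t_asc - t_ramp)
  vals <- c(rep(v_start, n_base), ramp)
  i0 <- n_base + 1L
  command_waveform("voltage_clamp", dt, vals, baseline_n = n_base,
                   epochs = list(ramp = c(i0, n_base + n_ramp),
                                 ramp_peak = i0 + round(t_asc / dt)))
}

#' Symmetric current bi-ramp command
#'
#' Triangular injected-current command from 0 pA to `peak` and back at
#' `rate`, after a baseline hold at 0 pA. The standard F-I protocol uses
#' 600 pA/s to a peak of 1500 pA (5 s up-and-down).
#'
#' @param rate Ramp speed in pA/s (> 0).
#' @param peak Peak current (pA, >= 0). `peak = 0` yields an all-zero
#'   waveform.
#' @param dt Sample interval (ms).
#' @param baseline_ms Pre-ramp hold at 0 pA (ms).
#' @return A current-clamp `command_waveform` with `ramp` epoch.
#' @export
make_current_biramp <- function(rate = 600, peak = 1500, dt = 0.1,
                                baseline_ms = 500) {
  if (!is.finite(rate) || rate <= 0) stop_invalid("rate must be positive (pA/s)")
  if (!is.finite(dt) || dt <= 0) stop_invalid("dt must be positive (ms)")
  if (!is.finite(peak) || peak < 0) stop_invalid("peak must be >= 0 (pA)")
  n_base <- round(baseline_ms / dt)
  if (peak == 0) {
    vals <- rep(0, max(n_base, 1L))
    return(command_waveform("current_clamp", dt, vals, baseline_n = n_base,
                            epochs = list(ramp = c(length(vals), length(vals)),
                                          ramp_peak = length(vals))))
  }
  r <- rate / 1000                         # pA/ms
  t_asc <- peak / r
  n_ramp <- round(2 * t_asc / dt) + 1L
  t_ramp <- (seq_len(n_ramp) - 1) * dt
  ramp <- r * pmin(t_ramp, 2 * t_asc - t_ramp)
  vals <- c(rep(0, n_base), ramp)
  i0 <- n_base + 1L
  command_waveform("current_clamp", dt, vals, baseline_n = n_base,
                   epochs = list(ramp = c(i0, n_base + n_ramp),
                                 ramp_peak = i0 + round(t_asc / dt)))
}

#' Family of small voltage steps
#'
#' One waveform per step amplitude: hold at `v_hold`, step to
#' `v_hold + amplitude` for `step_duration`, return to hold. Used to
#' estimate input conductance, leak current and capacitance.
#'
#' @param v_hold Holding potential (mV).
#' @param step_amplitudes Non-empty numeric vector of step amplitudes (mV).
#' @param step_duration Step length (ms).
#' @param dt Sample interval (ms).
#' @param baseline_ms Pre-step hold (ms).
#' @param post_ms Post-step hold (ms).
#' @return List of voltage-clamp `command_waveform`s, each with a `step`
#'   epoch.
#' @export
make_voltage_steps <- function(v_hold = -80, step_amplitudes = c(-10, -5, 5, 10),
                               step_duration = 500, dt = 0.1,
                               baseline_ms = 500, post_ms = 250) {
  if (length(step_amplitudes) < 1L)
    stop_invalid("step_amplitudes must be non-empty")
  if (!is.finite(dt) || dt <= 0) stop_invalid("dt must be positive (ms)")
  if (!is.finite(step_duration) || step_duration <= 0)
    stop_invalid("step_duration must be positive (ms)")
  lapply(step_amplitudes, function(a) {
    n_base <- round(baseline_ms / dt)
    n_step <- round(step_duration / dt)
    n_post <- round(post_ms / dt)
    vals <- c(rep(v_hold, n_base), rep(v_hold + a, n_step), rep(v_hold, n_post))
    command_waveform("voltage_clamp", dt, vals, baseline_n = n_base,
                     epochs = list(step = c(n_base + 1L, n_base + n_step)))
  })
}

#' Depolarizing current step
#'
#' Injected-current step of the given amplitude and duration after a 0 pA
#' baseline hold; used for the repetitive-firing assay (e.g. 1 nA for
#' 800 ms) and for rheobase series.
#'
#' @param amplitude Step amplitude (pA); 0 gives a zero waveform.
#' @param duration Step length (ms).
#' @param dt Sample interval (ms).
#' @param baseline_ms Pre-step hold (ms).
#' @param post_ms Post-step hold (ms).
#' @return A current-clamp `command_waveform` with a `step` epoch.
#' @export
make_current_step <- function(amplitude = 1000, duration = 800, dt = 0.1,
                              baseline_ms = 500, post_ms = 250) {
  if (!is.finite(dt) || dt <= 0) stop_invalid("dt must be positive (ms)")
  if (!is.finite(duration) || duration <= 0)
    stop_invalid("duration must be positive (ms)")
  n_base <- round(baseline_ms / dt)
  n_step <- round(duration / dt)
  n_post <- round(post_ms / dt)
  vals <- c(rep(0, n_base), rep(amplitude, n_step), rep(0, n_post))
  command_waveform("current_clamp", dt, vals, baseline_n = n_base,
                   epochs = list(step = c(n_base + 1L, n_base + n_step)))
}

#' Write a waveform to a two-column CSV (time_ms, command)
#'
#' @param wave A `command_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wave, path) {
  stopifnot(inherits(wave, "command_waveform"))
  data.table::fwrite(as.data.frame(wave), path)
  invisible(path)
}

# condition helpers -----------------------------------------------------------

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("picramp_invalid_parameter", "picramp_error")))
}

stop_protocol <- function(msg) {
  stop(errorCondition(msg, class = c("picramp_protocol_error", "picramp_error")))
}

stop_data <- function(msg) {
  stop(errorCondition(msg, class = c("picramp_insufficient_data", "picramp_error")))
}

stop_fit <- function(msg) {
  stop(errorCondition(msg, class = c("picramp_fit_error", "picramp_error")))
}
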