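#' Recorded trace
#'
#' A uniformly sampled (command, response) pair: in voltage clamp the
#' response is the measured clamp current (pA), in current clamp the
#' membrane voltage (mV). Traces carry the protocol epochs of the command
#' waveform they were recorded under, and — for synthetic traces — the
#' generating `cell_params` as attribute `ground_truth`.
#'
#' @param dt Sample interval (ms).
#' @param command Command samples (mV or pA per `mode`).
#' @param response Response samples, same length as `command`.
#' @param mode `"voltage_clamp"` or `"current_clamp"`.
#' @param epochs Named list of protocol segment index ranges.
#' @return An object of class `trace`.
#' @export
new_trace <- function(dt, command, response, mode, epochs = list()) {
  mode <- match.arg(mode, c("voltage_clamp", "current_clamp"))
  if (length(command) != length(response))
    stop_invalid("command and response must have equal length")
  if (!all(is.finite(response)))
    stop_invalid("response contains non-finite values")
  structure(list(dt = dt, command = as.numeric(command),
                 response = as.numeric(response), mode = mode,
                 epochs = epochs),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  un <- if (x$mode == "voltage_clamp") c("mV", "pA") else c("pA", "mV")
  cat(sprintf("<trace> %s, %d samples @ dt = %g ms (%.3f s)\n  command [%g, %g] %s; response [%.4g, %.4g] %s\n",
              x$mode, length(x$command), x$dt,
              length(x$command) * x$dt / 1000,
              min(x$command), max(x$command), un[1],
              min(x$response), max(x$response), un[2]))
  invisible(x)
}

#' @export
as.data.frame.trace <- function(x, ...) {
  data.frame(time_ms = (seq_along(x$command) - 1) * x$dt,
             command = x$command, response = x$response)
}

#' @export
plot.trace <- function(x, ...) {
  un <- if (x$mode == "voltage_clamp") c("command (mV)", "current (pA)")
        else c("command (pA)", "voltage (mV)")
  t_s <- (seq_along(x$command) - 1) * x$dt / 1000
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(t_s, x$response, type = "l", xlab = "time (s)", ylab = un[2], ...)
  graphics::plot(t_s, x$command, type = "l", xlab = "time (s)", ylab = un[1])
  invisible(x)
}

.resolve_seed <- function(seed, params) {
  if (is.null(seed)) params$rng_seed else as.integer(seed)
}

#' Simulate a voltage-clamp recording
#'
#' Ideal-clamp response to a voltage command:
#'   I(t) = G_leak (V - E_leak) + I_PIC(V) + I_cap(t) + noise,
#' where the capacitive transient is the command derivative filtered through
#' a single exponential of time constant C/G_leak (the whole-cell charging
#' transient), so a voltage step produces a decaying exponential of that
#' time constant and a ramp a constant C*dV/dt offset.
#'
#' @param params A `cell_params`.
#' @param cmd A voltage-clamp `command_waveform`.
#' @param seed Integer seed for the noise (default: the cell's `rng_seed`).
#' @return A voltage-clamp `trace` with `ground_truth` attribute.
#' @export
simulate_voltage_clamp <- function(params, cmd, seed = NULL) {
  stopifnot(inherits(params, "cell_params"), inherits(cmd, "command_waveform"))
  if (cmd$mode != "voltage_clamp")
    stop_protocol("voltage-clamp simulation requires a voltage-clamp command")
  v <- cmd$values
  tau <- params$C / params$G_leak
  a <- exp(-cmd$dt / tau)
  dv <- c(0, diff(v))
  icap <- as.numeric(stats::filter((params$C / tau) * dv, a, method = "recursive"))
  i <- params$G_leak * (v - params$E_leak) + pic_current(params, v) + icap
  if (params$noise_sd > 0) {
    set.seed(.resolve_seed(seed, params))
    i <- i + stats::rnorm(length(i), 0, params$noise_sd)
  }
  tr <- new_trace(cmd$dt, v, i, "voltage_clamp", cmd$epochs)
  attr(tr, "ground_truth") <- params
  tr
}

#' Simulate a current-clamp recording
#'
#' Forward-Euler integration of the membrane equation
#'   C dV/dt = -G_leak (V - E_leak) - I_PIC(V) + I_inj + noise
#' with the integrate-and-fire spike mechanism of [cell_params()] (stylized
#' spike to `ap_peak`, reset to `V_reset`, refractory hold `t_ref`, optional
#' slow spike-availability depletion). Integration runs at the command's
#' `dt`; the default protocol generators use 0.01 ms for current clamp.
#'
#' @param params A `cell_params`.
#' @param cmd A current-clamp `command_waveform`.
#' @param seed Integer seed for the noise (default: the cell's `rng_seed`).
#' @return A current-clamp `trace`; generator spike times (ms) are attached
#'   as attribute `spike_times_true`, the cell as `ground_truth`.
#' @export
simulate_current_clamp <- function(params, cmd, seed = NULL) {
  stopifnot(inherits(params, "cell_params"), inherits(cmd, "command_waveform"))
  if (cmd$mode != "current_clamp")
    stop_protocol("current-clamp simulation requires a current-clamp command")
  n <- length(cmd$values)
  noise <- if (params$noise_sd > 0) {
    set.seed(.resolve_seed(seed, params))
    stats::rnorm(n, 0, params$noise_sd)
  } else rep(0, n)
  out <- .cc_integrate(cmd$values, noise, cmd$dt,
                       params$C, params$G_leak, params$E_leak,
                       params$G_pic, params$V_half, params$k_act, params$E_pic,
                       params$V_T, params$V_reset, params$t_ref, params$ap_peak,
                       params$avail_use, params$avail_min, params$tau_avail,
                       params$E_leak)
  tr <- new_trace(cmd$dt, cmd$values, out$V, "current_clamp", cmd$epochs)
  attr(tr, "ground_truth") <- params
  attr(tr, "spike_times_true") <- (out$spike_idx - 1) * cmd$dt
  tr
}

# trace I/O -------------------------------------------------------------------

#' Write a trace as CSV plus JSON sidecar
#'
#' The CSV holds `time_ms, command, response`; the sidecar (`<path>.json`)
#' holds mode, dt, units, and — for synthetic traces — the ground-truth cell
#' parameters and epochs, so a run is fully reconstructable from disk.
#'
#' @param trace A `trace`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "trace"))
  data.table::fwrite(as.data.frame(trace), path)
  units <- if (trace$mode == "voltage_clamp") list(command = "mV", response = "pA")
           else list(command = "pA", response = "mV")
  gt <- attr(trace, "ground_truth")
  side <- list(mode = trace$mode, dt = trace$dt, units = units,
               epochs = trace$epochs,
               ground_truth = if (!is.null(gt)) unclass(gt))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#'
#' @param path CSV path (the `<path>.json` sidecar must exist).
#' @return A `trace`.
#' @export
read_trace_csv <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(path)) stop_data(sprintf("missing trace file: %s", path))
  if (!file.exists(side_path)) stop_data(sprintf("missing sidecar: %s", side_path))
  d <- data.table::fread(path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  epochs <- lapply(side$epochs, as.integer)
  tr <- new_trace(side$dt, d$command, d$response, side$mode, epochs)
  if (!is.null(side$ground_truth))
    attr(tr, "ground_truth") <- do.call(cell_params, side$ground_truth)
  tr
}
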