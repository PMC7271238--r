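# voltage-clamp analysis: input conductance, leak, capacitance, PIC

# index range of the step epoch; falls back to command inspection for traces
# lacking epoch metadata
.step_range <- function(trace) {
  if (!is.null(trace$epochs$step)) return(as.integer(trace$epochs$step))
  base <- trace$command[1]
  idx <- which(trace$command != base)
  if (!length(idx)) return(c(1L, length(trace$command)))  # constant command
  c(min(idx), max(idx))
}

# ascending-limb index range of the ramp epoch
.ascending_range <- function(trace) {
  if (!is.null(trace$epochs$ramp)) {
    c(as.integer(trace$epochs$ramp[1]), as.integer(trace$epochs$ramp_peak))
  } else {
    c(1L, which.max(trace$command)[1])
  }
}

#' Input conductance from a family of voltage steps
#'
#' Least-squares slope of the steady-state clamp current (mean over the last
#' 20% of the step) against the step command voltage. Around and below rest
#' the PIC is deactivated, so this slope estimates the leak (input)
#' conductance.
#'
#' @param step_traces List of voltage-clamp `trace`s at >= 2 distinct step
#'   levels.
#' @return Input conductance in nS.
#' @export
estimate_input_conductance <- function(step_traces) {
  if (inherits(step_traces, "trace")) step_traces <- list(step_traces)
  if (length(step_traces) < 2L)
    stop_data("need at least 2 voltage-step traces to estimate conductance")
  lev <- vapply(step_traces, function(tr) {
    if (tr$mode != "voltage_clamp") stop_protocol("voltage-clamp traces required")
    r <- .step_range(tr)
    w <- seq(r[1] + ceiling(0.8 * (r[2] - r[1])), r[2])
    c(mean(tr$command[w]), mean(tr$response[w]))
  }, numeric(2))
  v <- lev[1, ]; i <- lev[2, ]
  if (length(unique(round(v, 9))) < 2L)
    stop_data("need at least 2 distinct step levels")
  unname(stats::coef(stats::lm(i ~ v))[2])
}

#' Whole-cell capacitance from a voltage-step transient
#'
#' Fits a single exponential to the decaying capacitive transient after the
#' step onset and returns C = tau * g_leak, with g_leak taken from the
#' steady-state current change of the same trace. The measurement
#' convention (exponential transient fit) is a package choice; published
#' tables rarely state one.
#'
#' @param step_trace A voltage-clamp `trace` containing one step onset.
#' @return Capacitance in pF.
#' @export
estimate_capacitance <- function(step_trace) {
  stopifnot(inherits(step_trace, "trace"))
  if (step_trace$mode != "voltage_clamp")
    stop_protocol("voltage-clamp trace required")
  r <- .step_range(step_trace)
  if (r[1] <= 1L) stop_data("no pre-step baseline present")
  dt <- step_trace$dt
  pre <- seq_len(r[1] - 1L)
  ss_w <- seq(r[1] + ceiling(0.8 * (r[2] - r[1])), r[2])
  i_pre <- mean(step_trace$response[pre])
  i_ss <- mean(step_trace$response[ss_w])
  dv <- mean(step_trace$command[ss_w]) - mean(step_trace$command[pre])
  if (abs(dv) < 1e-9) stop_data("zero-amplitude step: no transient to fit")
  g <- (i_ss - i_pre) / dv
  idx <- seq(r[1], r[2])
  y <- step_trace$response[idx] - i_ss
  tt <- (seq_along(idx) - 1) * dt
  # transient must exist and decay monotonically (after light smoothing)
  amp0 <- y[1]
  if (abs(amp0) < max(4 * stats::sd(step_trace$response[pre] - i_pre), 1e-6))
    stop_fit("no capacitive transient detected (pure-resistor response)")
  k <- max(3L, min(25L, floor(length(y) / 50)))
  ys <- stats::filter(y, rep(1 / k, k), sides = 1)
  ys <- ys[!is.na(ys)]
  # decay check on the above-noise-floor part only: a genuine transient's
  # magnitude must trend monotonically down there
  floor_sd <- max(stats::sd(ys[seq(ceiling(0.8 * length(ys)), length(ys))]), 1e-9)
  seg <- abs(ys[abs(ys) > 3 * floor_sd])
  if (length(seg) >= 5L &&
      stats::cor(seq_along(seg), seg) > -0.3)
    stop_fit("capacitive transient is not monotone after smoothing")
  # log-linear start values on the early, clearly-above-noise part
  big <- which(abs(y) > abs(amp0) * 0.05)
  big <- big[big <= max(big[1], ceiling(length(y) / 2))]
  sgn <- sign(amp0)
  lf <- stats::lm(log(pmax(sgn * y[big], 1e-12)) ~ tt[big])
  tau0 <- max(dt, -1 / stats::coef(lf)[2])
  fit <- try(stats::nls(y ~ A * exp(-tt / tau), start = list(A = amp0, tau = tau0),
                        control = stats::nls.control(warnOnly = TRUE),
                        algorithm = "port",
                        lower = c(A = -Inf, tau = dt / 10)),
             silent = TRUE)
  tau <- if (inherits(fit, "try-error")) tau0 else stats::coef(fit)[["tau"]]
  unname(tau * abs(g))
}

#' Leak fit on a ramp's ascending limb
#'
#' Least-squares line of the clamp current against the command voltage over
#' a subthreshold window of the ascending limb, fitted before the PIC
#' activates. The fitted line (which also absorbs the constant capacitive
#' ramp offset) is what [extract_pic()] subtracts.
#'
#' @param ramp_trace A voltage-clamp bi-ramp `trace`.
#' @param window Voltage window `c(lo, hi)` in mV on the ascending limb;
#'   the default `c(-80, -60)` lies below reported PIC onset voltages.
#' @param settle_ms Ascending-limb samples within this many ms of the ramp
#'   start are excluded, so the capacitive settling transient at ramp onset
#'   does not tilt the fit.
#' @return An object of class `leak_fit`: `g_leak` (nS), `e_rev` (mV,
#'   x-intercept), `intercept` (pA), `window`, `rms_residual` (pA),
#'   `n_points`.
#' @export
fit_leak <- function(ramp_trace, window = c(-80, -60), settle_ms = 250) {
  stopifnot(inherits(ramp_trace, "trace"))
  if (ramp_trace$mode != "voltage_clamp")
    stop_protocol("voltage-clamp trace required")
  if (length(window) != 2L || window[1] >= window[2])
    stop_invalid("window must be c(lo, hi) with lo < hi")
  asc <- .ascending_range(ramp_trace)
  idx <- seq(asc[1], asc[2])
  v <- ramp_trace$command[idx]
  sel <- v >= window[1] & v <= window[2] &
    (seq_along(idx) - 1L) * ramp_trace$dt >= settle_ms
  if (sum(sel) < 10L)
    stop(errorCondition(
      sprintf("leak window [%g, %g] mV lies outside the ascending limb range [%g, %g]",
              window[1], window[2], min(v), max(v)),
      class = c("picramp_invalid_window", "picramp_error")))
  fit <- stats::lm(ramp_trace$response[idx][sel] ~ v[sel])
  b <- unname(stats::coef(fit))
  structure(list(g_leak = b[2], intercept = b[1],
                 e_rev = if (abs(b[2]) > 1e-12) -b[1] / b[2] else NA_real_,
                 window = window,
                 rms_residual = sqrt(mean(stats::residuals(fit)^2)),
                 n_points = sum(sel)),
            class = "leak_fit")
}

#' @export
print.leak_fit <- function(x, ...) {
  cat(sprintf("<leak_fit> g_leak = %.3f nS, e_rev = %.2f mV (window [%g, %g] mV, rms %.2f pA, n = %d)\n",
              x$g_leak, x$e_rev, x$window[1], x$window[2],
              x$rms_residual, x$n_points))
  invisible(x)
}

#' @export
coef.leak_fit <- function(object, ...) {
  c(intercept = object$intercept, g_leak = object$g_leak)
}

#' Extract the PIC from a leak-subtracted voltage bi-ramp
#'
#' Subtracts the fitted leak line from the ascending-limb clamp current and
#' measures the PIC as the minimum (most inward point) of the smoothed
#' leak-subtracted current: `amplitude` (pA, <= 0) and `peak_voltage` (the
#' command voltage there). `onset_voltage` is the lowest voltage at which
#' the smoothed leak-subtracted current falls below `onset_current` and
#' stays below it up to the minimum, provided it stays below for at least
#' `onset_sustain_ms`; otherwise the onset is flagged undefined (`NA`).
#'
#' @param ramp_trace A voltage-clamp bi-ramp `trace`.
#' @param leak A `leak_fit` from the same trace (default: fitted here with
#'   the default window).
#' @param onset_current Onset criterion (pA, default -10).
#' @param onset_sustain_ms Minimum time below criterion (ms, default 50).
#' @param smooth_n Moving-average width in samples (default 201).
#' @param exclude_start_ms Samples within this many ms of the ramp start are
#'   excluded from the search, so the capacitive settling transient at ramp
#'   onset is not mistaken for an inward current.
#' @return An object of class `pic_measure`: `amplitude`, `onset_voltage`,
#'   `peak_voltage`, `onset_defined`, `leak`.
#' @export
extract_pic <- function(ramp_trace, leak = fit_leak(ramp_trace),
                        onset_current = -10, onset_sustain_ms = 50,
                        smooth_n = 201, exclude_start_ms = 250) {
  stopifnot(inherits(ramp_trace, "trace"), inherits(leak, "leak_fit"))
  if (ramp_trace$mode != "voltage_clamp")
    stop_protocol("voltage-clamp trace required")
  asc <- .ascending_range(ramp_trace)
  idx <- seq(asc[1], asc[2])
  v <- ramp_trace$command[idx]
  ils <- ramp_trace$response[idx] - (leak$intercept + leak$g_leak * v)
  sm <- as.numeric(stats::filter(ils, rep(1 / smooth_n, smooth_n), sides = 2))
  # drop the smoothing edges and the ramp-start capacitive settling foot
  t_asc <- (seq_along(idx) - 1L) * ramp_trace$dt
  valid <- which(!is.na(sm) & t_asc >= exclude_start_ms)
  if (length(valid) < 2L) stop_data("ascending limb too short for PIC extraction")
  i_min <- valid[which.min(sm[valid])]
  amplitude <- min(sm[i_min], 0)
  peak_voltage <- v[i_min]
  onset_voltage <- NA_real_
  onset_defined <- FALSE
  below <- sm[valid] < onset_current & valid <= i_min
  if (amplitude < onset_current && any(below)) {
    upto <- valid[valid <= i_min]
    above <- upto[sm[upto] >= onset_current]
    j <- if (length(above)) max(above) + 1L else upto[1]
    sustained_ms <- (i_min - j + 1L) * ramp_trace$dt
    if (j <= i_min && sustained_ms >= onset_sustain_ms) {
      onset_voltage <- v[j]
      onset_defined <- TRUE
    }
  }
  if (amplitude >= 0) {
    amplitude <- 0
    peak_voltage <- NA_real_
  }
  structure(list(amplitude = amplitude, onset_voltage = onset_voltage,
                 peak_voltage = peak_voltage, onset_defined = onset_defined,
                 leak = leak),
            class = "pic_measure")
}

#' @export
print.pic_measure <- function(x, ...) {
  cat(sprintf("<pic_measure> amplitude = %.1f pA, peak at %s mV, onset %s\n",
              x$amplitude,
              if (is.na(x$peak_voltage)) "NA" else sprintf("%.1f", x$peak_voltage),
              if (x$onset_defined) sprintf("at %.1f mV", x$onset_voltage)
              else "undefined"))
  print(x$leak)
  invisible(x)
}
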