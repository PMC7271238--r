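# current-clamp analysis: spikes, RMP, F-I relationship, rheobase

#' Detect action potentials in a current-clamp trace
#'
#' Spikes are upward crossings of 0 mV reduced to their local maxima. The
#' per-spike voltage threshold is the voltage at which dV/dt first exceeds
#' `dvdt_threshold` in the rising phase before the peak (a common
#' convention).
#'
#' @param trace A current-clamp `trace`.
#' @param dvdt_threshold Threshold-detection criterion in mV/ms (default 10).
#' @return An object of class `spike_train`: `times` (ms), `peaks` (mV),
#'   `thresholds` (mV), `n`.
#' @export
detect_spikes <- function(trace, dvdt_threshold = 10) {
  stopifnot(inherits(trace, "trace"))
  if (trace$mode != "current_clamp")
    stop_protocol("current-clamp trace required")
  v <- trace$response
  dt <- trace$dt
  cross <- which(v[-1] >= 0 & v[-length(v)] < 0) + 1L
  peaks <- integer(0)
  for (i in cross) {
    j <- i
    while (j < length(v) && v[j + 1L] > v[j]) j <- j + 1L
    peaks <- c(peaks, j)
  }
  thr <- vapply(peaks, function(p) {
    dvdt <- diff(v[max(1L, p - round(20 / dt)):p]) / dt
    run <- which(dvdt >= dvdt_threshold)
    if (!length(run)) return(NA_real_)
    # walk back to the start of the final suprathreshold dV/dt run
    k <- max(run)
    while (k > 1L && dvdt[k - 1L] >= dvdt_threshold) k <- k - 1L
    v[max(1L, p - round(20 / dt)) + k - 1L]
  }, numeric(1))
  structure(list(times = (peaks - 1L) * dt, peaks = v[peaks],
                 thresholds = thr, n = length(peaks)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", x$n))
  if (x$n > 0)
    cat(sprintf("; mean peak %.1f mV, mean threshold %.1f mV, span %.1f-%.1f ms",
                mean(x$peaks), mean(x$thresholds, na.rm = TRUE),
                min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Resting membrane potential from a gap-free recording
#'
#' Mean membrane voltage over spike-free samples. Samples within
#' `exclude_ms` of a detected spike are masked before averaging.
#'
#' @param gapfree_trace A current-clamp `trace` (typically zero injected
#'   current).
#' @param exclude_ms Window `c(before, after)` around each spike to mask,
#'   in ms.
#' @return RMP in mV.
#' @export
measure_rmp <- function(gapfree_trace, exclude_ms = c(2, 30)) {
  stopifnot(inherits(gapfree_trace, "trace"))
  if (gapfree_trace$mode != "current_clamp")
    stop_protocol("current-clamp trace required")
  v <- gapfree_trace$response
  st <- detect_spikes(gapfree_trace)
  keep <- rep(TRUE, length(v))
  if (st$n > 0) {
    t <- (seq_along(v) - 1L) * gapfree_trace$dt
    for (ts in st$times)
      keep[t >= ts - exclude_ms[1] & t <= ts + exclude_ms[2]] <- FALSE
  }
  if (!any(keep)) stop_data("no spike-free samples to average")
  mean(v[keep])
}

#' Build the instantaneous frequency-current (F-I) relationship
#'
#' One point per adjacent spike pair: instantaneous frequency
#' f = 1000 / ISI (Hz) plotted against the injected current at the second
#' spike of the pair, tagged `ascending` or `descending` by whether that
#' spike precedes the command peak.
#'
#' @param trace A current-clamp `trace` recorded under a current bi-ramp.
#' @param cmd The `command_waveform` used (default: taken from the trace's
#'   own command samples and epochs).
#' @return An object of class `fi_curve`: a data.frame with columns
#'   `current_pA`, `freq_Hz`, `phase`, plus the detected `spike_train` as
#'   attribute `spikes`.
#' @export
build_fi <- function(trace, cmd = NULL) {
  stopifnot(inherits(trace, "trace"))
  st <- detect_spikes(trace)
  if (st$n < 2L)
    stop_data(sprintf("need at least 2 spikes to build an F-I curve (found %d)", st$n))
  command <- if (is.null(cmd)) trace$command else cmd$values
  epochs <- if (is.null(cmd)) trace$epochs else cmd$epochs
  peak_idx <- if (!is.null(epochs$ramp_peak)) epochs$ramp_peak
              else which.max(command)[1]
  t_peak <- (peak_idx - 1L) * trace$dt
  second <- st$times[-1]
  isi <- diff(st$times)
  idx2 <- round(second / trace$dt) + 1L
  out <- data.frame(current_pA = command[idx2],
                    freq_Hz = 1000 / isi,
                    phase = ifelse(second <= t_peak, "ascending", "descending"),
                    stringsAsFactors = FALSE)
  attr(out, "spikes") <- st
  class(out) <- c("fi_curve", "data.frame")
  out
}

#' @export
plot.fi_curve <- function(x, ...) {
  cols <- ifelse(x$phase == "ascending", "firebrick", "steelblue")
  graphics::plot(x$current_pA / 1000, x$freq_Hz, col = cols, pch = 16,
                 xlab = "injected current (nA)",
                 ylab = "instantaneous frequency (Hz)", ...)
  graphics::legend("topleft", legend = c("ascending", "descending"),
                   col = c("firebrick", "steelblue"), pch = 16, bty = "n")
  invisible(x)
}

#' Linear F-I fit with onset/offset currents
#'
#' Least-squares line per phase of the F-I relationship; slopes are
#' reported in Hz/nA. `I_on` and `I_off` are the injected currents at the
#' first and last spike of the ramp; `delta_I = I_off - I_on` by
#' definition.
#'
#' @param fi An `fi_curve`.
#' @param first_spike_current,last_spike_current I_on and I_off in pA
#'   (default: read from the spike train and command stored in `fi`).
#' @return An object of class `fi_fit`: `I_on`, `I_off`, `delta_I` (pA),
#'   `slope_asc`, `slope_desc` (Hz/nA, `NA` when a phase has < 2 points),
#'   `r2_asc`, `r2_desc`, `n_asc`, `n_desc`.
#' @export
fit_fi <- function(fi, first_spike_current = NULL, last_spike_current = NULL) {
  stopifnot(inherits(fi, "fi_curve"))
  phase_fit <- function(ph) {
    d <- fi[fi$phase == ph, ]
    if (nrow(d) < 2L || length(unique(d$current_pA)) < 2L)
      return(c(slope = NA_real_, r2 = NA_real_, n = nrow(d)))
    m <- stats::lm(freq_Hz ~ current_pA, data = d)
    # exactly collinear points are legitimate here; silence the perfect-fit
    # warning from summary.lm
    r2 <- suppressWarnings(summary(m)$r.squared)
    c(slope = unname(stats::coef(m)[2]) * 1000,   # Hz/pA -> Hz/nA
      r2 = r2, n = nrow(d))
  }
  a <- phase_fit("ascending"); d <- phase_fit("descending")
  ion <- first_spike_current
  ioff <- last_spike_current
  if (is.null(ion) || is.null(ioff)) {
    # endpoints of the full F-I point set: currents at first/last spike pair
    ion <- if (is.null(ion)) fi$current_pA[1] else ion
    ioff <- if (is.null(ioff)) fi$current_pA[nrow(fi)] else ioff
  }
  structure(list(I_on = ion, I_off = ioff, delta_I = ioff - ion,
                 slope_asc = a[["slope"]], slope_desc = d[["slope"]],
                 r2_asc = a[["r2"]], r2_desc = d[["r2"]],
                 n_asc = as.integer(a[["n"]]), n_desc = as.integer(d[["n"]])),
            class = "fi_fit")
}

#' @export
print.fi_fit <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", v)
  cat(sprintf(paste0("<fi_fit> I_on = %s pA, I_off = %s pA, delta_I = %s pA\n",
                     "  slope ascending %s Hz/nA (r2 %s, n %d); descending %s Hz/nA (r2 %s, n %d)\n"),
              fmt(x$I_on), fmt(x$I_off), fmt(x$delta_I),
              fmt(x$slope_asc), fmt(x$r2_asc), x$n_asc,
              fmt(x$slope_desc), fmt(x$r2_desc), x$n_desc))
  invisible(x)
}

#' @export
coef.fi_fit <- function(object, ...) {
  c(I_on = object$I_on, I_off = object$I_off, delta_I = object$delta_I,
    slope_asc = object$slope_asc, slope_desc = object$slope_desc)
}

#' Rheobase from a series of depolarizing current steps
#'
#' Smallest step amplitude that evokes at least one spike.
#'
#' @param step_traces List of current-clamp step `trace`s.
#' @return Step amplitude in pA, or `NA` (with a message attribute) when no
#'   step evokes a spike.
#' @export
measure_rheobase <- function(step_traces) {
  if (inherits(step_traces, "trace")) step_traces <- list(step_traces)
  if (!length(step_traces)) stop_data("no step traces supplied")
  amp <- vapply(step_traces, function(tr) {
    r <- .step_range(tr)
    max(tr$command[seq(r[1], r[2])])
  }, numeric(1))
  fired <- vapply(step_traces, function(tr) detect_spikes(tr)$n >= 1L, logical(1))
  if (!any(fired)) {
    out <- NA_real_
    attr(out, "not_found") <- TRUE
    return(out)
  }
  min(amp[fired])
}

#' Spike count during a prolonged current step
#'
#' Counts detected spikes inside the step window; the repetitive-firing
#' assay behind the hypoexcitability classification (a healthy motoneuron
#' fires repetitively during a 1 nA, 800 ms step; a hypoexcitable one fires
#' at most a single spike).
#'
#' @param step_trace A current-clamp step `trace`.
#' @return Integer spike count.
#' @export
assess_repetitive_firing <- function(step_trace) {
  stopifnot(inherits(step_trace, "trace"))
  r <- .step_range(step_trace)
  st <- detect_spikes(step_trace)
  if (st$n == 0L) return(0L)
  t0 <- (r[1] - 1L) * step_trace$dt
  t1 <- (r[2] - 1L) * step_trace$dt
  sum(st$times >= t0 & st$times <= t1)
}
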