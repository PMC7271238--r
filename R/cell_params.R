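#' Generative parameters for one model motoneuron
#'
#' Ground truth for the synthetic-data generator: a single-compartment
#' membrane with leak conductance, a non-inactivating Boltzmann PIC
#' conductance, capacitance, and an integrate-and-fire spike mechanism with
#' stylized spikes. In the package unit system (ms, mV, pA, nS, pF) the
#' membrane equation is
#'
#'   C dV/dt = -G_leak (V - E_leak) - I_PIC(V) + I_inj
#'
#' with I_PIC(V) = G_pic * m(V) * (V - E_pic),
#' m(V) = 1 / (1 + exp((V_half - V) / k_act)).
#'
#' The defaults for `V_half`, `k_act` and `E_pic` were solved so that the
#' emergent PIC onset voltage (about -46 mV at a -200 pA amplitude, with the
#' -10 pA onset criterion) and peak-current voltage (about -21 mV) sit at the
#' values reported for neonatal mouse motoneurons.
#'
#' The spike mechanism additionally carries a slow spike-availability
#' resource used to model hypoexcitable cells: each spike multiplies the
#' availability by `(1 - avail_use)`, a spike is only emitted while
#' availability >= `avail_min`, and availability recovers towards 1 with time
#' constant `tau_avail`. With `avail_use = 0` (the default) the mechanism is
#' inert and the cell is a plain leaky integrate-and-fire neuron with PIC,
#' for which the closed-form firing rate [lif_rate()] is exact.
#'
#' @param C Capacitance (pF).
#' @param G_leak Leak conductance (nS); equals the input conductance at rest.
#' @param E_leak Leak reversal = resting membrane potential (mV).
#' @param G_pic Maximal PIC conductance (nS); 0 disables the PIC.
#' @param V_half PIC half-activation voltage (mV).
#' @param k_act PIC activation slope (mV, > 0).
#' @param E_pic PIC reversal potential (mV); must exceed `V_half`.
#' @param V_T Spike threshold (mV).
#' @param V_reset Post-spike reset voltage (mV).
#' @param t_ref Lumped refractory/AHP period (ms).
#' @param ap_peak Stylized spike overshoot (mV).
#' @param noise_sd Gaussian current-noise SD (pA).
#' @param avail_use Fraction of spike availability consumed per spike
#'   (0 = no depletion).
#' @param avail_min Minimum availability required to emit a spike.
#' @param tau_avail Availability recovery time constant (ms).
#' @param rng_seed Integer seed attached to the cell (used when simulation
#'   functions are called without an explicit seed).
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(C = 332, G_leak = 24, E_leak = -59, G_pic = 0,
                        V_half = -31.2, k_act = 4.3, E_pic = 30,
                        V_T = -30, V_reset = -50, t_ref = 25, ap_peak = 29,
                        noise_sd = 0, avail_use = 0, avail_min = 0.5,
                        tau_avail = 30000, rng_seed = 1L) {
  p <- list(C = C, G_leak = G_leak, E_leak = E_leak, G_pic = G_pic,
            V_half = V_half, k_act = k_act, E_pic = E_pic,
            V_T = V_T, V_reset = V_reset, t_ref = t_ref, ap_peak = ap_peak,
            noise_sd = noise_sd, avail_use = avail_use,
            avail_min = avail_min, tau_avail = tau_avail,
            rng_seed = as.integer(rng_seed))
  ok <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
               logical(1))
  if (!all(ok)) stop_invalid("all cell parameters must be finite scalars")
  if (p$G_leak <= 0) stop_invalid("G_leak must be positive")
  if (p$C <= 0) stop_invalid("C must be positive")
  if (p$k_act <= 0) stop_invalid("k_act must be positive")
  if (p$E_pic <= p$V_half) stop_invalid("E_pic must exceed V_half")
  if (!(p$E_leak < p$V_T && p$V_T < p$ap_peak))
    stop_invalid("need E_leak < V_T < ap_peak")
  if (p$noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (p$avail_use < 0 || p$avail_use >= 1)
    stop_invalid("avail_use must lie in [0, 1)")
  structure(p, class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<cell_params> C = %g pF, G_leak = %g nS, E_leak = %g mV\n",
    "  PIC: G_pic = %.3g nS (V_half = %g, k_act = %g, E_pic = %g mV)\n",
    "  spikes: V_T = %g, V_reset = %g mV, t_ref = %g ms, peak = %g mV\n",
    "  noise_sd = %g pA%s\n"),
    x$C, x$G_leak, x$E_leak, x$G_pic, x$V_half, x$k_act, x$E_pic,
    x$V_T, x$V_reset, x$t_ref, x$ap_peak, x$noise_sd,
    if (x$avail_use > 0)
      sprintf(", availability depletion %g (min %g, tau %g ms)",
              x$avail_use, x$avail_min, x$tau_avail) else ""))
  invisible(x)
}

#' Steady-state PIC current
#'
#' I_PIC(V) = G_pic * m(V) * (V - E_pic) with the Boltzmann activation
#' m(V) = 1/(1 + exp((V_half - V)/k_act)). Inward (depolarizing) current is
#' negative; the current is <= 0 for all V < E_pic.
#'
#' @param params A `cell_params`.
#' @param v Membrane voltage(s), mV. Vectorized.
#' @return PIC current in pA, same length as `v`.
#' @export
pic_current <- function(params, v) {
  stopifnot(inherits(params, "cell_params"))
  m <- 1 / (1 + exp((params$V_half - v) / params$k_act))
  params$G_pic * m * (v - params$E_pic)
}

#' Voltage of the PIC current minimum on a ramp range
#'
#' Dense-grid search for the voltage in `[v_lo, v_hi]` at which the PIC is
#' most inward, and the per-nS unit amplitude there. Internal workhorse for
#' [calibrate_gpic()] and the amplitude oracle in tests.
#'
#' @param params A `cell_params` (its `G_pic` is ignored for `unit_min`).
#' @param v_lo,v_hi Search range (mV).
#' @param dv Grid spacing (mV).
#' @return List with `v_peak` (mV), `unit_min` (pA per nS of G_pic, <= 0)
#'   and `amplitude` (pA, at the cell's own G_pic).
#' @export
pic_grid_minimum <- function(params, v_lo = -80, v_hi = 10, dv = 0.01) {
  v <- seq(v_lo, v_hi, by = dv)
  m <- 1 / (1 + exp((params$V_half - v) / params$k_act))
  unit <- m * (v - params$E_pic)           # pA per nS
  i <- which.min(unit)
  list(v_peak = v[i], unit_min = min(unit[i], 0),
       amplitude = params$G_pic * unit[i])
}

#' Solve G_pic for a target PIC amplitude
#'
#' Returns the maximal PIC conductance for which the most-inward PIC current
#' over the standard ramp range equals `target_pic_amplitude`. Since the PIC
#' is linear in G_pic, the solution is `target / unit_min` where `unit_min`
#' is the grid-search minimum of the unit-conductance PIC.
#'
#' @param target_pic_amplitude Target amplitude in pA; must be negative
#'   (inward).
#' @param params A `cell_params` supplying the activation parameters.
#' @param v_lo,v_hi Ramp voltage range searched (mV).
#' @return G_pic in nS.
#' @export
calibrate_gpic <- function(target_pic_amplitude, params = cell_params(),
                           v_lo = -80, v_hi = 10) {
  if (!is.finite(target_pic_amplitude) || target_pic_amplitude >= 0)
    stop_invalid("target PIC amplitude must be negative (inward, pA)")
  unit_min <- pic_grid_minimum(params, v_lo, v_hi)$unit_min
  if (unit_min >= 0)
    stop_invalid("PIC activation produces no inward current on this range")
  target_pic_amplitude / unit_min
}

#' Closed-form leaky integrate-and-fire firing rate
#'
#' Steady-state firing rate of the spike mechanism for a constant injected
#' current with `G_pic = 0`:
#'   f = 1000 / (t_ref + (C/G) * log((I/G + E - V_reset)/(I/G + E - V_T)))
#' in Hz. Returns 0 below rheobase (I <= G * (V_T - E_leak)).
#'
#' @param params A `cell_params` (PIC ignored).
#' @param I Injected current (pA). Vectorized.
#' @return Firing rate in Hz.
#' @export
lif_rate <- function(params, I) {
  stopifnot(inherits(params, "cell_params"))
  x <- I / params$G_leak + params$E_leak
  f <- rep(0, length(I))
  sup <- x > params$V_T
  tau <- params$C / params$G_leak
  f[sup] <- 1000 / (params$t_ref +
                      tau * log((x[sup] - params$V_reset) / (x[sup] - params$V_T)))
  f
}

#' Quasi-static rheobase of the model cell
#'
#' Smallest constant current for which the membrane can reach the spike
#' threshold: I* = G_leak * (V_T - E_leak) + I_PIC(V_T) (the PIC term is
#' negative and lowers the rheobase). For slowly rising inputs the PIC may
#' pull the effective rheobase slightly lower than this bound if its
#' activation midpoint lies below V_T.
#'
#' @param params A `cell_params`.
#' @return Current in pA.
#' @export
quasi_static_rheobase <- function(params) {
  v <- seq(params$E_leak, params$V_T, by = 0.01)
  # the injected current must clear the net outward current at every
  # subthreshold voltage for V to reach V_T quasi-statically
  max(params$G_leak * (v - params$E_leak) + pic_current(params, v))
}
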