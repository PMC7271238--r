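# shared fixtures: preset cells and shortened protocols built in code

# noiseless WT-preset cell with PIC calibrated to the given amplitude
preset_cell <- function(amplitude = -200, noise_sd = 0, ...) {
  base <- cell_params(noise_sd = noise_sd, ...)
  cell_params(G_pic = calibrate_gpic(amplitude, base), noise_sd = noise_sd, ...)
}

# standard PIC voltage bi-ramp at a coarser dt for cheap tests
quick_vramp <- function(dt = 0.2) make_voltage_biramp(-80, 10, 20, dt = dt)

# hand-built current-clamp trace with stylized spikes at given times (ms)
spiky_trace <- function(spike_times, dt = 0.1, total_ms = 3000, v_rest = -60,
                        peak = 29, command = NULL) {
  n <- round(total_ms / dt)
  v <- rep(v_rest, n)
  idx <- round(spike_times / dt) + 1L
  v[pmax(idx - 1L, 1L)] <- -40        # rising-phase sample ahead of the peak
  v[idx] <- peak
  if (is.null(command)) command <- rep(0, n)
  new_trace(dt, command, v, "current_clamp")
}

expect_picramp_error <- function(expr, class = "picramp_error") {
  expect_error(expr, class = class)
}
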