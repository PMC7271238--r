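# input conductance, capacitance, leak fitting, PIC extraction

test_that("input conductance recovers the generator leak conductance", {
  p <- cell_params(G_leak = 24, G_pic = 0, noise_sd = 0)
  steps <- make_voltage_steps(-80, c(-10, -5, 5, 10), 500, dt = 0.2)
  trs <- lapply(steps, simulate_voltage_clamp, params = p)
  expect_equal(estimate_input_conductance(trs), 24, tolerance = 0.1 / 24)
  # identical currents at all steps: slope 0
  flat <- lapply(c(-90, -85, -70), function(v) {
    cmd <- c(rep(-80, 100), rep(v, 400))
    new_trace(0.1, cmd, rep(5, 500), "voltage_clamp",
              epochs = list(step = c(101L, 500L)))
  })
  expect_equal(estimate_input_conductance(flat), 0)
  # constant offset current leaves the slope unchanged
  shifted <- lapply(trs, function(tr) {
    tr$response <- tr$response + 40
    tr
  })
  expect_equal(estimate_input_conductance(shifted),
               estimate_input_conductance(trs), tolerance = 1e-9)
  expect_picramp_error(estimate_input_conductance(trs[1]),
                       "picramp_insufficient_data")
})

test_that("capacitance comes from the transient time constant", {
  step <- make_voltage_steps(-80, -10, 500, dt = 0.1)[[1]]
  p <- cell_params(C = 332, G_leak = 24, G_pic = 0, noise_sd = 0)
  expect_equal(estimate_capacitance(simulate_voltage_clamp(p, step)), 332,
               tolerance = 3 / 332)
  # tau doubles when C doubles at fixed G
  p2 <- cell_params(C = 664, G_leak = 24, G_pic = 0, noise_sd = 0)
  expect_equal(estimate_capacitance(simulate_voltage_clamp(p2, step)), 664,
               tolerance = 6 / 664)
  # a pure-resistor trace has no transient to fit
  v <- step$values
  ohmic <- new_trace(step$dt, v, 24 * (v + 59), "voltage_clamp", step$epochs)
  expect_picramp_error(estimate_capacitance(ohmic), "picramp_fit_error")
})

test_that("leak fit recovers the leak line and reports residuals", {
  leaky <- cell_params(G_pic = 0, noise_sd = 0)
  tr <- simulate_voltage_clamp(leaky, quick_vramp())
  lk <- fit_leak(tr, c(-75, -55))
  expect_equal(lk$g_leak, leaky$G_leak, tolerance = 1e-6)
  expect_lt(lk$rms_residual, 0.01)
  # WT preset (with PIC): default window still within 2% of generator truth
  p <- preset_cell(-200)
  lk2 <- fit_leak(simulate_voltage_clamp(p, quick_vramp()))
  expect_equal(lk2$g_leak, p$G_leak, tolerance = 0.02)
  # rms residual tracks the noise level on noisy pure-leak data
  noisy <- cell_params(G_pic = 0, noise_sd = 5)
  lk3 <- fit_leak(simulate_voltage_clamp(noisy, quick_vramp(), seed = 14))
  expect_lt(lk3$rms_residual, 5 * 1.5)
  expect_picramp_error(fit_leak(tr, c(40, 60)), "picramp_invalid_window")
})

test_that("extract_pic measures amplitude, peak and onset voltages", {
  # null PIC: amplitude ~0 and onset undefined
  leaky <- cell_params(G_pic = 0, noise_sd = 0)
  tr0 <- simulate_voltage_clamp(leaky, quick_vramp())
  pm0 <- extract_pic(tr0, fit_leak(tr0), smooth_n = 101)
  expect_equal(pm0$amplitude, 0, tolerance = 1e-6)
  expect_false(pm0$onset_defined)
  # mSOD1-calibrated PIC: amplitude within 4 pA of -357
  pm <- preset_cell(-357)
  trm <- simulate_voltage_clamp(pm, quick_vramp())
  picm <- extract_pic(trm, fit_leak(trm), smooth_n = 101)
  expect_equal(picm$amplitude, -357, tolerance = 4 / 357)
  # WT defaults: emergent onset near -46 mV, peak near -21 mV
  pw <- preset_cell(-200)
  trw <- simulate_voltage_clamp(pw, quick_vramp())
  picw <- extract_pic(trw, fit_leak(trw), smooth_n = 101)
  expect_equal(picw$onset_voltage, -46, tolerance = 2 / 46)
  expect_equal(picw$peak_voltage, -21, tolerance = 2 / 21)
  expect_true(picw$amplitude <= 0)
  expect_lte(picw$onset_voltage, picw$peak_voltage)
})

test_that("PIC measures are invariant to adding leak to the response", {
  p <- preset_cell(-250)
  tr <- simulate_voltage_clamp(p, quick_vramp())
  lk <- fit_leak(tr)
  pm <- extract_pic(tr, lk, smooth_n = 101)
  cshift <- 7                                # extra leak conductance, nS
  tr2 <- tr
  tr2$response <- tr$response + cshift * (tr$command - lk$e_rev)
  lk2 <- fit_leak(tr2)
  expect_equal(lk2$g_leak, lk$g_leak + cshift, tolerance = 1e-6)
  pm2 <- extract_pic(tr2, lk2, smooth_n = 101)
  expect_equal(pm2$amplitude, pm$amplitude, tolerance = 1e-6)
  expect_equal(pm2$peak_voltage, pm$peak_voltage, tolerance = 1e-6)
})

test_that("PIC amplitude is non-increasing in G_pic", {
  ramp <- quick_vramp()
  amps <- vapply(seq(0.5, 8, length.out = 8), function(gp) {
    p <- cell_params(G_pic = gp, noise_sd = 0)
    tr <- simulate_voltage_clamp(p, ramp)
    extract_pic(tr, fit_leak(tr), smooth_n = 101)$amplitude
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("amplitude extraction is robust to recording noise", {
  p <- preset_cell(-200, noise_sd = 5)
  ramp <- quick_vramp()
  errs <- vapply(1:60, function(s) {
    tr <- simulate_voltage_clamp(p, ramp, seed = s)
    abs(extract_pic(tr, fit_leak(tr), smooth_n = 101)$amplitude - (-200))
  }, numeric(1))
  expect_lt(stats::median(errs), 5)
})
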