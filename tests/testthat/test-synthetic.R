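# conductance-model generator: PIC model, clamp simulations, cohorts

test_that("pic_current follows the Boltzmann model", {
  p0 <- cell_params(G_pic = 0)
  expect_equal(pic_current(p0, seq(-80, 10, 5)), rep(0, 19))
  p <- cell_params(G_pic = 4)
  expect_equal(pic_current(p, p$V_half),
               4 * 0.5 * (p$V_half - p$E_pic))
  # activation is monotone increasing
  v <- seq(-80, 10, 0.5)
  m <- pic_current(p, v) / (v - p$E_pic)
  expect_true(all(diff(m) > 0))
  expect_true(all(pic_current(p, v[v < p$E_pic]) <= 0))
})

test_that("grid-search PIC minimum agrees with a 1-d minimizer oracle", {
  p <- preset_cell(-200)
  oracle <- stats::optimize(function(v) pic_current(p, v), c(-80, 10))
  gm <- pic_grid_minimum(p)
  expect_equal(gm$amplitude, oracle$objective, tolerance = 0.1 / 200)
  expect_equal(gm$v_peak, oracle$minimum, tolerance = 0.05)
})

test_that("voltage-clamp response is leak + PIC + capacitive transient", {
  leaky <- cell_params(G_pic = 0, noise_sd = 0)
  w <- quick_vramp()
  tr <- simulate_voltage_clamp(leaky, w)
  # pure leak: response is linear in V on each limb (constant capacitive
  # offset per limb) once the ramp-onset transient has settled
  asc <- seq(w$epochs$ramp[1] + 2000, w$epochs$ramp_peak)
  fit <- stats::lm(tr$response[asc] ~ tr$command[asc])
  expect_lt(max(abs(stats::residuals(fit))), 1e-6)
  expect_equal(unname(stats::coef(fit)[2]), leaky$G_leak, tolerance = 1e-9)
  # constant command at E_leak gives zero current
  hold <- command_waveform("voltage_clamp", 0.1, rep(leaky$E_leak, 1000))
  expect_equal(max(abs(simulate_voltage_clamp(leaky, hold)$response)), 0)
  # mode mismatch is a protocol error
  expect_picramp_error(
    simulate_voltage_clamp(leaky, make_current_step(100, 100)),
    "picramp_protocol_error")
})

test_that("leak-subtracted ramp minimum matches the PIC grid oracle", {
  # simulator correctness in isolation: subtract the generator's own leak
  # line (slope G_leak, intercept carrying E_leak and the constant C*dV/dt
  # ramp offset), leaving exactly the PIC
  p <- preset_cell(-250)
  w <- quick_vramp()
  tr <- simulate_voltage_clamp(p, w)
  rate_mv_ms <- 20 / 1000
  true_leak <- structure(
    list(g_leak = p$G_leak,
         intercept = -p$G_leak * p$E_leak + p$C * rate_mv_ms,
         e_rev = p$E_leak, window = c(-80, -60), rms_residual = 0,
         n_points = 0L),
    class = "leak_fit")
  pm <- extract_pic(tr, true_leak, smooth_n = 101)
  expect_equal(pm$amplitude, pic_grid_minimum(p)$amplitude, tolerance = 0.5 / 250)
})

test_that("current-clamp simulation reproduces the closed-form LIF rate", {
  p <- cell_params(G_pic = 0, noise_sd = 0)
  # no input: settles at rest, no spikes
  rest <- simulate_current_clamp(p, make_current_step(0, 500, dt = 0.1))
  expect_equal(rest$response[length(rest$response)], p$E_leak, tolerance = 1e-6)
  expect_equal(detect_spikes(rest)$n, 0)
  # suprathreshold step: steady-state rate within 2% of closed form
  stp <- make_current_step(1000, 3000, dt = 0.01)
  st <- detect_spikes(simulate_current_clamp(p, stp))
  isi <- diff(st$times)
  steady <- utils::tail(isi, 5)
  expect_equal(1000 / mean(steady), lif_rate(p, 1000), tolerance = 0.02)
})

test_that("spike times converge as dt is halved", {
  # each spike time is quantized to the step grid, so refinement moves the
  # k-th spike by at most ~k steps (one step of slack per preceding period)
  p <- cell_params(G_pic = 0, noise_sd = 0)
  t1 <- attr(simulate_current_clamp(p, make_current_step(900, 400, dt = 0.02)),
             "spike_times_true")
  t2 <- attr(simulate_current_clamp(p, make_current_step(900, 400, dt = 0.01)),
             "spike_times_true")
  expect_equal(length(t1), length(t2))
  expect_lt(abs(t1[1] - t2[1]), 0.02)
  expect_true(all(abs(t1 - t2) <= seq_along(t1) * 0.02 + 1e-9))
  # and the refined run is closer to the closed-form period
  T_exact <- 1000 / lif_rate(p, 900)
  expect_lt(abs(mean(diff(t2)) - T_exact), abs(mean(diff(t1)) - T_exact) + 0.01)
})

test_that("simulations are reproducible under a fixed seed", {
  p <- preset_cell(-200, noise_sd = 5)
  w <- quick_vramp()
  expect_identical(simulate_voltage_clamp(p, w, seed = 9)$response,
                   simulate_voltage_clamp(p, w, seed = 9)$response)
  stp <- make_current_step(800, 200, dt = 0.05)
  expect_identical(simulate_current_clamp(p, stp, seed = 9)$response,
                   simulate_current_clamp(p, stp, seed = 9)$response)
})

test_that("cohort draws converge to the spec means and are seeded", {
  wt <- motoneuron_presets()[["WT"]]
  cells <- make_cohort(wt, 10000, seed = 5)
  g <- vapply(cells, `[[`, numeric(1), "G_leak")
  expect_equal(mean(g), 24, tolerance = 0.5 / 24)
  expect_identical(make_cohort(wt, 5, seed = 3), make_cohort(wt, 5, seed = 3))
  # zero-SD spec collapses to the mean cell
  frozen <- group_spec("frozen", G_leak = c(24, 0), E_leak = c(-59, 0),
                       C = c(332, 0), ap_peak = c(29, 0), V_T = c(-30, 0),
                       pic_amplitude = c(-200, 0))
  cc <- make_cohort(frozen, 3, seed = 1)
  expect_equal(cc[[1]]$G_pic, cc[[2]]$G_pic)
  expect_equal(cc[[2]]$C, cc[[3]]$C)
})

test_that("calibrate_gpic hits its target and is linear", {
  base <- cell_params()
  for (target in c(-200, -357, -229, -87)) {
    g <- calibrate_gpic(target, base)
    p <- cell_params(G_pic = g)
    expect_equal(pic_grid_minimum(p)$amplitude, target, tolerance = 0.5 / abs(target))
  }
  expect_equal(calibrate_gpic(-400, base), 2 * calibrate_gpic(-200, base))
  expect_picramp_error(calibrate_gpic(50, base), "picramp_invalid_parameter")
})

test_that("soma-volume sampling matches the group distributions", {
  pres <- motoneuron_presets()
  v <- sample_soma_volumes(pres[["WT"]], 1e5, seed = 2)
  expect_equal(mean(v), 11812.62, tolerance = 0.01)
  vm <- sample_soma_volumes(pres[["mSOD1"]], 1e5, seed = 2)
  expect_equal(mean(vm > 15000), 0.381, tolerance = 0.011 / 0.381)
  # degenerate mixture = single normal
  s1 <- group_spec("x", soma = list(weights = 1, means = 100, sds = 5))
  s2 <- group_spec("x", soma = list(weights = c(1, 0), means = c(100, 900),
                                    sds = c(5, 5)))
  expect_equal(mean(sample_soma_volumes(s1, 5000, seed = 4)),
               mean(sample_soma_volumes(s2, 5000, seed = 4)), tolerance = 0.05)
  expect_identical(sample_soma_volumes(s1, 10, seed = 8),
                   sample_soma_volumes(s1, 10, seed = 8))
})

test_that("noiseless end-to-end recovery is exact to within tolerance", {
  # any noiseless cell: pipeline-extracted G_in within 1% of G_leak and PIC
  # amplitude within max(1%, 2 pA) of the grid-search oracle
  set.seed(21)
  steps <- make_voltage_steps(dt = 0.2)
  ramp <- quick_vramp()
  for (i in 1:8) {
    p <- cell_params(C = runif(1, 150, 500), G_leak = runif(1, 10, 45),
                     E_leak = runif(1, -65, -52), noise_sd = 0)
    p <- cell_params(C = p$C, G_leak = p$G_leak, E_leak = p$E_leak,
                     G_pic = calibrate_gpic(runif(1, -400, -60), p),
                     noise_sd = 0)
    gin <- estimate_input_conductance(lapply(steps, simulate_voltage_clamp,
                                             params = p))
    expect_equal(gin, p$G_leak, tolerance = 0.01)
    tr <- simulate_voltage_clamp(p, ramp)
    pm <- extract_pic(tr, fit_leak(tr), smooth_n = 101)
    truth <- pic_grid_minimum(p)$amplitude
    expect_lt(abs(pm$amplitude - truth), max(0.01 * abs(truth), 2))
  }
})
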