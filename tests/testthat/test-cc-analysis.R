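# spike detection, RMP, F-I construction and fitting, rheobase

test_that("spike detection finds stylized spikes and their shape", {
  # subthreshold trace: empty train
  sub <- new_trace(0.1, rep(0, 1000), rep(-60, 1000), "current_clamp")
  expect_equal(detect_spikes(sub)$n, 0)
  # generator spike times recovered within one sample
  p <- cell_params(G_pic = 0, noise_sd = 0)
  tr <- simulate_current_clamp(p, make_current_step(1000, 1500, dt = 0.02))
  st <- detect_spikes(tr)
  truth <- attr(tr, "spike_times_true")
  expect_equal(st$n, length(truth))
  expect_lt(max(abs(st$times - truth)), 0.02 + 1e-9)
  # detected peaks sit at the stylized overshoot, thresholds near V_T
  expect_equal(mean(st$peaks), 29, tolerance = 0.5 / 29)
  expect_equal(mean(st$thresholds), p$V_T, tolerance = 0.1)
  expect_true(all(st$peaks > st$thresholds))
  expect_true(all(diff(st$times) > 0))
})

test_that("RMP is the mean of spike-free samples", {
  const <- new_trace(0.1, rep(0, 5000), rep(-59, 5000), "current_clamp")
  expect_equal(measure_rmp(const), -59)
  # masking oracle: spikes excised by hand give the same mean
  tr <- spiky_trace(c(500, 1200, 2100), v_rest = -59)
  v <- tr$response
  spike_free <- new_trace(0.1, tr$command[v < -50], v[v < -50], "current_clamp")
  expect_equal(measure_rmp(tr), mean(spike_free$response), tolerance = 0.1 / 59)
  # zero-mean noise: recovered within 3 SEM
  set.seed(3)
  n <- 20000
  noise <- rnorm(n, 0, 2)
  noisy <- new_trace(0.1, rep(0, n), -59 + noise, "current_clamp")
  expect_equal(measure_rmp(noisy), -59, tolerance = 3 * 2 / sqrt(n) / 59)
})

test_that("F-I points are 1/ISI against current at the second spike", {
  # two spikes 100 ms apart: single 10 Hz point
  cmd <- seq(0, 1500, length.out = 30000)
  tr2 <- spiky_trace(c(1000, 1100), command = cmd)
  fi <- build_fi(tr2)
  expect_equal(nrow(fi), 1)
  expect_equal(fi$freq_Hz, 10)
  expect_equal(fi$current_pA, cmd[11001])
  # constant-rate train on a ramp: all frequencies equal
  tr20 <- spiky_trace(seq(200, 2800, by = 50), command = cmd)
  fi20 <- build_fi(tr20)
  expect_true(all(abs(fi20$freq_Hz - 20) < 0.5))
  # no descending-limb spikes: only ascending points
  w <- make_current_biramp(600, 1500, dt = 0.1)
  early <- spiky_trace(c(600, 700, 800), total_ms = length(w$values) * 0.1,
                       command = w$values)
  early$epochs <- w$epochs
  expect_true(all(build_fi(early)$phase == "ascending"))
  one <- spiky_trace(1000, command = cmd)
  expect_picramp_error(build_fi(one), "picramp_insufficient_data")
})

test_that("F-I fits recover slopes and the delta-I identity", {
  # points exactly on a 34 Hz/nA line fit exactly
  cur <- seq(500, 1400, by = 100)
  fi <- structure(data.frame(current_pA = rep(cur, 2),
                             freq_Hz = rep(10 + 34 * (cur / 1000), 2),
                             phase = rep(c("ascending", "descending"),
                                         each = length(cur))),
                  class = c("fi_curve", "data.frame"))
  ft <- fit_fi(fi, 445, 508)
  expect_equal(ft$slope_asc, 34)
  expect_equal(ft$slope_desc, 34)
  expect_equal(ft$delta_I, 508 - 445)
  expect_equal(ft$r2_asc, 1)
  # I_on = I_off gives delta_I = 0
  expect_equal(fit_fi(fi, 500, 500)$delta_I, 0)
  # a phase with < 2 points is flagged undefined, the other still fits
  fi_asc <- structure(fi[fi$phase == "ascending", ],
                      class = c("fi_curve", "data.frame"))
  ft2 <- fit_fi(fi_asc, 445, 508)
  expect_true(is.na(ft2$slope_desc))
  expect_equal(ft2$slope_asc, 34)
})

test_that("LIF ascending F-I slope matches the closed-form derivative", {
  p <- cell_params(G_pic = 0, noise_sd = 0)
  tr <- simulate_current_clamp(p, make_current_biramp(600, 1500, dt = 0.01))
  fi <- build_fi(tr)
  asc <- fi[fi$phase == "ascending", ]
  # mid-range window away from onset curvature and the ramp peak
  lo <- stats::quantile(asc$current_pA, 0.4)
  hi <- stats::quantile(asc$current_pA, 0.9)
  mid <- asc[asc$current_pA >= lo & asc$current_pA <= hi, ]
  slope <- unname(stats::coef(stats::lm(freq_Hz ~ current_pA, mid))[2]) * 1000
  i0 <- mean(mid$current_pA)
  deriv <- (lif_rate(p, i0 + 5) - lif_rate(p, i0 - 5)) / 10 * 1000
  expect_equal(slope, deriv, tolerance = 0.05)
})

test_that("slopes recovered across a LIF cohort track the closed form", {
  set.seed(17)
  cmd <- make_current_biramp(600, 1500, dt = 0.02)
  got <- want <- numeric(0)
  for (i in 1:12) {
    p <- cell_params(G_leak = runif(1, 15, 35), E_leak = runif(1, -64, -55),
                     C = runif(1, 250, 420), G_pic = 0, noise_sd = 0)
    fi <- build_fi(simulate_current_clamp(p, cmd))
    asc <- fi[fi$phase == "ascending", ]
    lo <- stats::quantile(asc$current_pA, 0.4)
    hi <- stats::quantile(asc$current_pA, 0.9)
    mid <- asc[asc$current_pA >= lo & asc$current_pA <= hi, ]
    got <- c(got, stats::coef(stats::lm(freq_Hz ~ current_pA, mid))[2] * 1000)
    i0 <- mean(mid$current_pA)
    want <- c(want, (lif_rate(p, i0 + 5) - lif_rate(p, i0 - 5)) / 10 * 1000)
  }
  expect_gt(stats::cor(got, want), 0.99)
})

test_that("rheobase is the smallest spiking step", {
  p <- cell_params(G_pic = 0, noise_sd = 0)
  analytic <- p$G_leak * (p$V_T - p$E_leak)          # 696 pA
  grid <- seq(200, 1400, by = 100)
  mk <- function(amps) lapply(amps, function(a)
    simulate_current_clamp(p, make_current_step(a, 800, dt = 0.05)))
  rb <- measure_rheobase(mk(grid))
  expect_equal(rb, min(grid[grid >= analytic]))
  # refining the grid approaches the analytic value from above
  fine <- seq(600, 800, by = 10)
  rb_fine <- measure_rheobase(mk(fine))
  expect_lte(rb_fine, rb)
  expect_gte(rb_fine, analytic)
  # all-subthreshold series: not-found flag
  none <- measure_rheobase(mk(c(100, 200)))
  expect_true(is.na(none))
  expect_true(attr(none, "not_found"))
})

test_that("repetitive-firing counts separate normal from hypoexcitable cells", {
  stp <- make_current_step(1000, 800, dt = 0.01)
  wt <- preset_cell(-200)
  expect_gte(assess_repetitive_firing(simulate_current_clamp(wt, stp)), 2)
  hypo <- make_cohort(motoneuron_presets(0)[["mSOD1+PF-hypo"]], 1, seed = 6)[[1]]
  expect_lte(assess_repetitive_firing(simulate_current_clamp(hypo, stp)), 1)
  zero <- make_current_step(0, 800, dt = 0.05)
  expect_equal(assess_repetitive_firing(simulate_current_clamp(wt, zero)), 0)
})

test_that("F-I frequencies are invariant to uniform time shifts", {
  cmd <- seq(0, 1500, length.out = 30000)
  t0 <- seq(500, 2000, by = 80)
  f1 <- build_fi(spiky_trace(t0, command = cmd))
  f2 <- build_fi(spiky_trace(t0 + 37, command = cmd))
  expect_equal(f1$freq_Hz, f2$freq_Hz, tolerance = 1e-9)
})
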