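test_that("P3 model trace follows the delayed-Gaussian formula", {
  p <- p3_params(400, 10, 0.004)
  expect_equal(p3_model_trace(p, c(0, 0.004)), c(0, 0))
  # E*S = 1e4 s^-2, t - td = 0.01 s: -400 * (1 - e^-1)
  p2 <- p3_params(400, 1e4 / 10^2.07, 0.004)
  expect_equal(p3_model_trace(p2, 0.014), -400 * (1 - exp(-1)),
               tolerance = 1e-12)
  # saturation limit
  p3 <- p3_params(400, 1e5, 0.004)
  expect_equal(p3_model_trace(p3, 0.5), -400, tolerance = 1e-8)
})

test_that("P3 trace is monotone non-increasing and bounded for random parameters", {
  set.seed(21)
  t <- seq(-0.02, 0.62, by = 1 / 4000)
  for (i in 1:25) {
    p <- p3_params(runif(1, 10, 1000), exp(runif(1, log(1), log(1e4))),
                   runif(1, 0, 0.012))
    tr <- p3_model_trace(p, t)
    expect_true(all(diff(tr) <= 1e-9))
    expect_true(all(tr >= -p$rm_p3_uV - 1e-9))
    expect_true(all(tr[t <= p$t_delay_s] == 0))
  }
})

test_that("fit recovers a pure P3 model from its own output", {
  t <- -0.02 + (0:2559) / 4000
  p_true <- p3_params(400, 10, 0.004)
  w <- erg_waveform(p3_model_trace(p_true, t))
  # pure model: no b-wave, so the whole leading edge is usable
  fit <- fit_p3(w, fit_window_s = c(0.003, 0.150))
  expect_equal(fit$rm_p3_uV, 400, tolerance = 1e-3)
  expect_equal(fit$sensitivity_S, 10, tolerance = 1e-3)
  expect_equal(fit$t_delay_s, 0.004, tolerance = 1e-3)
  expect_lt(fit$sse, 1e-4)
})

test_that("waveforms without an a-wave are rejected", {
  w <- erg_waveform(rep(0, 2560))
  expect_error(fit_p3(w), "no measurable a-wave")
  set.seed(5)
  w2 <- erg_waveform(rnorm(2560, 0, 2))   # noise only
  expect_error(fit_p3(w2), "no measurable a-wave")
})

test_that("subtracting the P3 behaves as raw minus model", {
  t <- -0.02 + (0:2559) / 4000
  p <- p3_params(350, 450, 0.0035)
  w <- erg_waveform(p3_model_trace(p, t))
  expect_equal(subtract_p3(w, p), rep(0, 2560), tolerance = 1e-12)
  # rm = 0 model leaves the waveform untouched
  p0 <- p3_params(0, 450, 0.0035)
  expect_equal(subtract_p3(w, p0), w$samples_uV)
})

test_that("subtracting the true P3 removes the a-wave leading edge", {
  params <- waveform_params()
  w <- simulate_waveform(params, seed = 17)
  truth <- p3_params(params$rm_p3_uV, params$sensitivity_S, params$t_delay_s)
  resid <- subtract_p3(w, truth)
  t <- erg_times(w)
  seg <- t > params$t_delay_s & t < params$t_delay_s + 0.015
  expect_gt(min(resid[seg]), -3 * params$noise_sd_uV)
})

test_that("a fit carries its grid and refuses a mismatched waveform", {
  w <- simulate_waveform(waveform_params(), seed = 2)
  fit <- fit_p3(w)
  w_short <- erg_waveform(w$samples_uV[1:2000], fs_hz = w$fs_hz, t0_s = w$t0_s)
  expect_error(subtract_p3(w_short, fit), "grid mismatch")
})
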