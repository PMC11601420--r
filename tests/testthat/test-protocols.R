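test_that("trapezoid AP train is measured exactly", {
  fx <- trapezoid_trace(n_beats = 3, CL = 500, apd = 200)
  ser <- measure_apd(fx$trace, stim_times = fx$stim_times)
  expect_true(all(ser$captured))
  expect_false(any(ser$censored))
  expect_equal(ser$apd, rep(200, 3), tolerance = 0.5)
  expect_equal(ser$di[1:2], rep(300, 2), tolerance = 0.5)
})

test_that("a resting trace yields no detected beats", {
  tr <- data.frame(t = seq(0, 1000, by = 0.5), v = -85)
  ser <- measure_apd(tr, stim_times = c(100, 600))
  expect_true(all(!ser$captured))
})

test_that("APD90 crossing is interpolated to the analytic intersection", {
  # rest -85, rise to +20 at t=0, hold to t=100, linear fall to -85 at t=310
  t <- seq(-50, 400, by = 0.5)
  v <- ifelse(t < 0, -85, ifelse(t <= 100, 20, pmax(20 - 0.5 * (t - 100), -85)))
  ser <- measure_apd(data.frame(t = t, v = v),
                     threshold_mode = "percent_repol", stim_times = 0)
  # 90% repolarization level: 20 - 0.9*105 = -74.5, reached at t = 289
  expect_equal(ser$apd[1], 289, tolerance = 0.5)
  # fixed -40 mV crossing at t = 220 precedes the 90% crossing
  ser40 <- measure_apd(data.frame(t = t, v = v), stim_times = 0)
  expect_equal(ser40$apd[1], 220, tolerance = 0.5)
  expect_lt(ser40$apd[1], ser$apd[1])
})

test_that("beats that never repolarize are censored and excluded from stats", {
  fx <- trapezoid_trace(n_beats = 2, CL = 400, apd = 200)
  tr <- fx$trace
  # second AP never comes down within the trace
  tr$v[tr$t > 400] <- 20
  ser <- measure_apd(tr, stim_times = fx$stim_times)
  expect_false(ser$censored[1])
  expect_true(ser$censored[2])
  st <- apd_statistics(rbind(ser, ser))  # 2 uncensored copies
  expect_equal(st$n, 2)
  expect_equal(st$n_censored, 2)
})

test_that("APD statistics use the population sigma convention", {
  ser <- data.frame(apd = c(200, 200, 200), captured = TRUE, censored = FALSE)
  st <- apd_statistics(ser)
  expect_equal(st$sigma, 0)
  expect_equal(st$cv, 0)
  ser2 <- data.frame(apd = c(100, 300), captured = TRUE, censored = FALSE)
  st2 <- apd_statistics(ser2)
  expect_equal(st2$mean, 200)
  expect_equal(st2$sigma, 100)   # population convention, divisor n
  expect_equal(st2$cv, 50)
  expect_error(apd_statistics(data.frame(apd = 1, captured = TRUE,
                                         censored = FALSE)),
               "undefined")
})

test_that("EAD notch detector fires on a notched plateau and not on a dome", {
  t <- seq(-20, 600, by = 0.5)
  smooth <- ifelse(t < 0, -85,
                   ifelse(t <= 300, 20 - 0.15 * t, pmax(-25 - (t - 300), -85)))
  notched <- smooth
  i <- t >= 150 & t <= 250
  notched[i] <- smooth[i] + 8 * sin(pi * (t[i] - 150) / 100)^2 - 8 *
    (t[i] < 200) * sin(pi * (t[i] - 150) / 50)^2
  expect_false(detect_ead(data.frame(t = t, v = smooth), stim_times = 0))
  expect_true(detect_ead(data.frame(t = t, v = notched), stim_times = 0))
})

test_that("electrotonic length follows the diffusion scaling", {
  expect_equal(electrotonic_length(1e-4, 500), sqrt(0.05))
  expect_equal(round(electrotonic_length(1e-4, 500), 1), 0.2)
  expect_equal(electrotonic_length(1e-4, 0), 0)
  expect_equal(electrotonic_length(1e-4, 2000),
               2 * electrotonic_length(1e-4, 500))
})

test_that("single-CL sweep degenerates to the steady-state protocol", {
  p <- ead_params()
  bif <- dynamic_pacing_sweep(p, CLs = 420, beats_per_CL = 8, record_last = 3,
                              mode = mode_det)
  expect_equal(unique(bif$CL), 420)
  expect_equal(nrow(bif), 3)
  expect_true(all(bif$captured))
})

test_that("S1S2 trials are independent and consistent at S2 = S1", {
  p <- ead_params()
  pts <- s1s2_restitution(p, S1 = 450, s2_list = c(450, 500), beats_S1 = 6,
                          tail_ms = 500)
  # S2 = S1 reproduces the steady-state point; adding later S2 values does not
  # perturb earlier ones
  pts2 <- s1s2_restitution(p, S1 = 450, s2_list = c(450), beats_S1 = 6,
                           tail_ms = 500)
  expect_equal(pts$apd[1], pts2$apd[1], tolerance = 1e-9)
  expect_equal(pts$di[1], pts2$di[1], tolerance = 1e-9)
  expect_false(any(pts$blocked))
})
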