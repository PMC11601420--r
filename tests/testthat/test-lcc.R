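test_that("Ca-inactivation factor matches its Hill form", {
  expect_equal(ca_inactivation_factor(2, 2), 0.5)       # cb = cth
  expect_equal(ca_inactivation_factor(2 / 3, 2), 0.1)   # cb = cth/3
  expect_gt(ca_inactivation_factor(1e5, 2), 0.999)      # saturates at 1
  expect_error(ca_inactivation_factor(-1, 2), "invalid")
})

test_that("inactivation rates combine baseline and Ca-dependent parts", {
  p <- ead_params("default", a24o = 0.01, a34o = 0.01, aca = 0.09)
  # spark-on channels use FCa = 1 exactly
  expect_equal(unname(inactivation_rates(0.1, p, spark_on = TRUE)["a24"]), 0.10)
  # ACa = 0 removes the Ca term entirely
  p0 <- ead_params("default", a24o = 0.02, a34o = 0.03, aca = 0)
  expect_equal(unname(inactivation_rates(5, p0)), c(0.02, 0.03))
  # monotone nondecreasing in cb
  cbs <- seq(0.05, 20, length.out = 50)
  a24 <- vapply(cbs, function(cb) inactivation_rates(cb, p)["a24"], numeric(1))
  expect_true(all(diff(a24) >= 0))
})

test_that("master equation preserves probability and stays in [0,1]", {
  p <- ead_params()
  occ <- lcc_state()
  out <- cpp_lcc_step(unclass(occ), -20, 0.5, 0.01, 1 / 30, unclass(p),
                      0.1, 1e5)
  expect_equal(sum(out), 1, tolerance = 1e-6)
  expect_true(all(out >= -1e-9 & out <= 1 + 1e-9))
})

test_that("all-rates-zero step is the identity", {
  p <- params_quiescent()
  occ <- lcc_state(c(0.2, 0.1, 0.3, 0.15, 0.05, 0.05, 0.05, 0.04, 0.03, 0.03))
  out <- step_lcc(occ, -20, 0.5, 0, 0, p, 0.1, n_steps = 100)
  expect_equal(unclass(out), unclass(occ), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("isolated O<->OS exchange reaches the two-state equilibrium", {
  p <- params_quiescent()
  occ <- rep(0, 10)
  occ[3] <- 1  # all in O
  ab <- 0.02
  bb <- 1 / 30
  out <- cpp_lcc_step(occ, 0, 0.5, ab, bb, unclass(p), 0.05, 20000)
  os_frac <- out[8] / (out[3] + out[8])
  expect_equal(os_frac, ab / (ab + bb), tolerance = 1e-6)
})

test_that("L-type current is linear in open fraction and reverses with voltage", {
  p <- ead_params()
  zero <- lcc_current(lcc_state(), -10, 0.5, p)  # all closed
  expect_equal(zero$ical, 0)
  occ1 <- rep(0, 10); occ1[3] <- 0.05; occ1[1] <- 0.95
  occ2 <- rep(0, 10); occ2[3] <- 0.10; occ2[1] <- 0.90
  i1 <- cpp_lcc_current(occ1, -10, 0.5, unclass(p))$ical
  i2 <- cpp_lcc_current(occ2, -10, 0.5, unclass(p))$ical
  expect_equal(i2, 2 * i1, tolerance = 1e-9)
  expect_lt(i1, 0)  # inward at plateau voltages
  # driving force vanishes at the GHK reversal for the spark-off pool:
  # cb*exp(2V/rtf) = 0.341 Cao
  cb <- 1
  v_rev <- p$rtf / 2 * log(0.341 * p$cao / (cb * 1e-3))
  occ_off <- rep(0, 10); occ_off[3] <- 0.1; occ_off[1] <- 0.9
  i_rev <- cpp_lcc_current(occ_off, v_rev, cb, unclass(p))$ical
  i_mid <- cpp_lcc_current(occ_off, 0, cb, unclass(p))$ical
  expect_lt(abs(i_rev), abs(i_mid) * 0.01)
})

test_that("reducing Ca-induced inactivation increases integrated L-type current", {
  # fixed AP-clamp waveform and fixed cb course; ACa 0.15 -> 0.09 must raise
  # the time-integrated inward current magnitude
  clamp <- function(aca) {
    p <- unclass(ead_params("default", aca = aca))
    occ <- c(1, rep(0, 9))
    tt <- seq(0, 300, by = 0.1)
    v <- ifelse(tt < 2, -80 + 50 * tt, pmax(25 - 0.25 * tt, -80))
    cb <- 0.2 + 2.5 * exp(-tt / 80) * (1 - exp(-tt / 5))
    tot <- 0
    for (i in seq_along(tt)) {
      occ <- cpp_lcc_step(occ, v[i], cb[i], 0.01, 1 / 30, p, 0.1, 1)
      tot <- tot + cpp_lcc_current(occ, v[i], cb[i], p)$ical * 0.1
    }
    tot
  }
  q15 <- clamp(0.15)
  q09 <- clamp(0.09)
  expect_lt(q09, q15)          # more negative (inward) charge
  expect_gt(abs(q09), abs(q15))
})
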