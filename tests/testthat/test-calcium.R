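test_that("junctional release flux follows gb * csrb * pb", {
  expect_equal(release_flux_junctional(1000, 0, 0.001), 0)
  expect_equal(release_flux_junctional(1000, 0.5, 0.001), 0.5)
  # linear in pb
  expect_equal(release_flux_junctional(700, 0.4, 0.02),
               2 * release_flux_junctional(700, 0.2, 0.02))
})

test_that("diffusive and uptake fluxes vanish where they must", {
  p <- ead_params()
  ca <- ca_state(cb = 0.5, ci = 0.5, csrb = 700, csri = 700)
  fl <- compute_all_fluxes(ca, spark_state(0, 4000), 0, 0, p)
  expect_equal(unname(fl["jdsr"]), 0)   # uniform SR
  expect_equal(unname(fl["jdc"]), 0)    # uniform cytosol
  expect_equal(unname(fl["jri"]), 0)    # NJ release off by default
  # Hill uptake vanishes at zero substrate
  ca0 <- ca_state(cb = 1e-9, ci = 1e-9)
  fl0 <- compute_all_fluxes(ca0, spark_state(0, 4000), 0, 0, p)
  expect_lt(unname(fl0["jupb"]), 1e-12)
  # release moves SR -> cytosol (nonnegative), uptake cytosol -> SR
  fl2 <- compute_all_fluxes(ca_state(cb = 2, ci = 1, csrb = 400, csri = 800),
                            spark_state(1000, 4000), 0.5, -0.2, p)
  expect_gte(unname(fl2["jrb"]), 0)
  expect_gte(unname(fl2["jupb"]), 0)
  expect_gt(unname(fl2["jdsr"]), 0)  # NJ SR feeds depleted junctional SR
  expect_gt(unname(fl2["jdc"]), 0)   # junctional cytosol feeds bulk
})

test_that("zero fluxes leave the state unchanged", {
  p <- ead_params()
  ca <- ca_state(0.2, 0.18, 750, 820)
  zero <- compute_all_fluxes(ca, spark_state(0, 4000), 0, 0, p) * 0
  out <- step_calcium(ca, zero, p, 0.05)
  expect_equal(unclass(out), unclass(ca))
})

test_that("closed cell conserves buffer-weighted total Ca over 1e4 steps", {
  p <- ead_params()
  ca <- ca_state(cb = 1.5, ci = 0.4, csrb = 300, csri = 900)
  q0 <- total_ca_content(ca, p)
  pb <- 0.15
  for (i in seq_len(1e4)) {
    fl <- cpp_ca_fluxes(unclass(ca), pb, 0, 0, unclass(p))  # membrane off
    out <- cpp_ca_step(unclass(ca), fl, unclass(p), 0.05)
    ca <- ca_state(out[["cb"]], out[["ci"]], out[["csrb"]], out[["csri"]])
    pb <- pb * 0.999
  }
  expect_equal(total_ca_content(ca, p), q0, tolerance = 1e-6)
})

test_that("pure SR-SR exchange relaxes to the volume-weighted mean", {
  p <- params_quiescent()
  p$tau_sr <- 30
  ca <- ca_state(cb = 0.2, ci = 0.2, csrb = 200, csri = 1000)
  dt <- 0.01
  n <- 20000
  for (i in seq_len(n)) {
    fl <- cpp_ca_fluxes(unclass(ca), 0, 0, 0, unclass(p))
    out <- cpp_ca_step(unclass(ca), fl, unclass(p), dt)
    ca <- ca_state(out[["cb"]], out[["ci"]], out[["csrb"]], out[["csri"]])
  }
  # closed form of the discrete recurrence: the concentration difference
  # contracts by (1 - lam*dt) each step, lam = (buf_csrb + buf_csri*vsrb/vsri)/tau
  lam <- (p$buf_csrb + p$buf_csri * p$vsrb / p$vsri) / p$tau_sr
  d0 <- 1000 - 200
  d_exp <- d0 * (1 - lam * dt)^n
  expect_equal(d_exp, d0 * exp(-lam * n * dt), tolerance = 5e-3)
  expect_equal(ca$csri - ca$csrb, d_exp, tolerance = 1e-3)
  # volume-weighted mean invariant
  m0 <- (p$vsrb * 200 + p$vsri * 1000) / (p$vsrb + p$vsri)
  m1 <- (p$vsrb * ca$csrb + p$vsri * ca$csri) / (p$vsrb + p$vsri)
  expect_equal(m1, m0, tolerance = 1e-9)
})

test_that("concentrations stay positive across the supported timestep range", {
  p <- ead_params()
  for (dt in c(0.01, 0.1)) {
    ca <- ca_state(0.1, 0.1, 900, 900)
    ok <- TRUE
    for (i in seq_len(2000)) {
      fl <- cpp_ca_fluxes(unclass(ca), 0.3, 0.5, -0.3, unclass(p))
      out <- cpp_ca_step(unclass(ca), fl, unclass(p), dt)
      if (any(out <= 0)) { ok <- FALSE; break }
      ca <- ca_state(out[["cb"]], out[["ci"]], out[["csrb"]], out[["csri"]])
    }
    expect_true(ok)
  }
})
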