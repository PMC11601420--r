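test_that("absorbing and saturated states never move", {
  # no recruitment channel and nothing to extinguish
  s <- spark_state(0, 4000)
  r <- spark_rates(0, 0.05)
  for (k in 1:20) s <- step_spark_counts_stochastic(s, r, 0.1, seed = 3,
                                                    epoch = k)
  expect_identical(s$nb, 0L)

  # saturated with no extinction
  s <- spark_state(4000, 4000)
  traj <- spark_trajectory(s, spark_rates(0.5, 1e-12), 0.1, n_steps = 200,
                           seed = 4)
  expect_true(all(traj == 4000L))
})

test_that("recruitment increments match the analytic binomial mean", {
  # Nb = 4000, nb = 1000, alpha = 0.01/ms, dt = 0.1 ms: E[dn+] = 3000*0.001 = 3
  n_rep <- 1e5
  draws <- cpp_binom_stream(n_rep, 3000L, 0.001, seed = 11)
  se <- sqrt(3000 * 0.001 * 0.999 / n_rep)
  expect_lt(abs(mean(draws) - 3), 3 * se)
})

test_that("binomial sampler matches mean and variance over both regimes", {
  n_rep <- 1e5
  for (cfg in list(c(3000, 0.001), c(200, 0.3), c(5000, 0.45), c(50, 0.9))) {
    n <- cfg[1]; p <- cfg[2]
    draws <- cpp_binom_stream(n_rep, as.integer(n), p, seed = 17)
    m <- n * p
    v <- n * p * (1 - p)
    expect_lt(abs(mean(draws) - m), 4 * sqrt(v / n_rep))
    # variance of the sample variance ~ 2 v^2 / n (normal approx)
    expect_lt(abs(var(draws) - v), 4 * sqrt(2 * v^2 / n_rep) + 4 * sqrt(v) / n_rep)
  }
})

test_that("counts stay within [0, Nb] over long trajectories at harsh rates", {
  s <- spark_state(2000, 4000)
  traj <- spark_trajectory(s, spark_rates(5, 5), 0.5, n_steps = 1e5, seed = 5)
  expect_true(all(traj >= 0 & traj <= 4000))
})

test_that("oversized success probabilities are subdivided or refused", {
  s <- spark_state(10, 100)
  r <- spark_rates(20, 0.01)
  expect_error(step_spark_counts_stochastic(s, r, 0.1, subdivide = FALSE),
               "timestep too large")
  out <- step_spark_counts_stochastic(s, r, 0.1, seed = 1)  # subdivides
  expect_true(out$nb >= 0 && out$nb <= 100)
  expect_error(step_spark_counts_stochastic(s, r, -0.1), "invalid")
})

test_that("identical seeds give bitwise identical spark trajectories", {
  s <- spark_state(100, 4000)
  r <- spark_rates(0.02, 1 / 30)
  t1 <- spark_trajectory(s, r, 0.1, n_steps = 5000, seed = 42)
  t2 <- spark_trajectory(s, r, 0.1, n_steps = 5000, seed = 42)
  t3 <- spark_trajectory(s, r, 0.1, n_steps = 5000, seed = 43)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
})

test_that("deterministic spark fraction follows the closed-form exponential", {
  # alpha = 0, beta = 0.05/ms from pb = 0.3: pb(20 ms) = 0.3 exp(-1)
  r <- spark_rates(0, 0.05)
  dt <- 1e-4
  pb <- 0.3
  for (i in seq_len(20 / dt)) pb <- step_spark_fraction_deterministic(pb, r, dt)
  expect_lt(abs(pb - pb_exact(0.3, 0, 0.05, 20)), 1e-6)

  # steady state at alpha = beta is 1/2 with zero derivative
  r2 <- spark_rates(0.04, 0.04)
  expect_equal(step_spark_fraction_deterministic(0.5, r2, 0.1), 0.5)
  # absorbing at zero without recruitment
  expect_equal(step_spark_fraction_deterministic(0, spark_rates(0, 0.1), 0.1), 0)
  expect_error(step_spark_fraction_deterministic(1.2, r2, 0.1), "invalid")
})

test_that("stochastic trajectory converges to the mean-field limit at large Nb", {
  # identical prescribed alpha(t) time course; Nb = 1e5 within 1% RMS of ODE
  dt <- 0.1
  n <- 4000
  tt <- (1:n) * dt
  alpha <- 0.05 * exp(-tt / 60) + 0.002
  beta <- 1 / 30
  Nb <- 1e5
  traj <- cpp_spark_trajectory(0L, as.integer(Nb), alpha, beta, dt, seed = 9)
  pb_stoch <- traj[-1] / Nb
  pb_ode <- numeric(n)
  pb <- 0
  for (i in 1:n) {
    pb <- pb + dt * (alpha[i] * (1 - pb) - beta * pb)
    pb_ode[i] <- pb
  }
  rms <- sqrt(mean((pb_stoch - pb_ode)^2))
  expect_lt(rms / max(pb_ode), 0.01)
})

test_that("recruitment rate is LCC-gated, load-sigmoidal and linear in alpha0", {
  p <- ead_params()
  expect_equal(spark_recruitment_rate(0, 800, p), 0)
  c1 <- spark_recruitment_rate(0.1, 300, p)
  c2 <- spark_recruitment_rate(0.1, 900, p)
  expect_lte(c1, c2)
  p2 <- p; p2$alpha0 <- 2 * p$alpha0
  expect_equal(spark_recruitment_rate(0.1, 500, p2),
               2 * spark_recruitment_rate(0.1, 500, p))
})
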