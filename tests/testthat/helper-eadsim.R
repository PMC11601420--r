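# Shared fixtures and small oracles used across the suite.

# quick deterministic/stochastic modes
mode_det <- ead_mode("deterministic")

# parameters with every internal rate switched off: useful for identity tests
params_quiescent <- function() {
  ead_params("default",
             k12 = 0, k23 = 0, r42a = 0, r42b = 0, r43a = 0, r43b = 0,
             a24o = 0, a34o = 0, aca = 0, alpha0 = 0, gb = 0, vup_b = 0, vup_i = 0,
             tau_c = 1e12, tau_sr = 1e12, conv_ica = 0, conv_ncx = 0)
}

# closed-form solution of the mean-field spark ODE with constant rates
pb_exact <- function(pb0, alpha, beta, t) {
  pinf <- if (alpha + beta > 0) alpha / (alpha + beta) else pb0
  pinf + (pb0 - pinf) * exp(-(alpha + beta) * t)
}

# natural cubic spline oracle: solve the tridiagonal second-derivative system
# directly (independent of stats::splinefun)
natural_spline_eval <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 3 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  cc <- solve(A, rhs)
  b <- dd <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    b[i] <- (y[i + 1] - y[i]) / h[i] - h[i] * (2 * cc[i] + cc[i + 1]) / 3
    dd[i] <- (cc[i + 1] - cc[i]) / (3 * h[i])
  }
  vapply(xout, function(xx) {
    i <- max(1, min(n - 1, findInterval(xx, x)))
    dx <- xx - x[i]
    y[i] + b[i] * dx + cc[i] * dx^2 + dd[i] * dx^3
  }, numeric(1))
}

# synthetic trapezoid AP train (exact APD ground truth)
trapezoid_trace <- function(n_beats = 3, CL = 500, apd = 200, dt = 0.5) {
  generate_fixture("toy_trace", n_beats = n_beats, CL = CL, apd_ms = apd,
                   dt = dt)
}
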