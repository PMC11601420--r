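test_that("spline interpolates knots exactly and clamps outside the domain", {
  pts <- generate_fixture("toy_restitution")$points
  map <- fit_restitution_spline(pts)
  expect_equal(map$F(pts$di), pts$apd, tolerance = 1e-9)
  expect_equal(map$F(pts$di[1] - 100), pts$apd[1])     # clamped
  expect_equal(map$F(max(pts$di) + 50), pts$apd[nrow(pts)])
  expect_error(fit_restitution_spline(data.frame(di = c(1, 1, 2, 3),
                                                 apd = 1:4)), "duplicate")
})

test_that("natural spline of collinear points reproduces the line", {
  pts <- data.frame(di = c(50, 150, 300, 420), apd = 100 + 0.4 * c(50, 150, 300, 420))
  map <- fit_restitution_spline(pts)
  mids <- c(100, 225, 360)
  expect_equal(map$F(mids), 100 + 0.4 * mids, tolerance = 1e-9)
})

test_that("spline evaluation matches an independent tridiagonal solve", {
  pts <- data.frame(di = c(40, 120, 260, 380, 470),
                    apd = c(150, 180, 240, 420, 460))
  map <- fit_restitution_spline(pts)
  xs <- seq(45, 465, by = 12)
  oracle <- natural_spline_eval(pts$di, pts$apd, xs)
  expect_equal(map$F(xs), oracle, tolerance = 1e-8)
})

test_that("a flat map is an immediate period-1 fixed point", {
  pts <- data.frame(di = c(50, 150, 300, 450), apd = 200)
  map <- fit_restitution_spline(pts)
  tr <- iterate_map(map, T = 500, DI0 = 100, n_max = 50)
  expect_equal(tr$status, "converged_period1")
  expect_true(all(abs(tr$apd - 200) < 1e-9))
  expect_equal(tail(tr$di, 1), 300, tolerance = 1e-9)
})

test_that("linear-map iteration matches the closed-form fixed point", {
  a <- 120; b <- 0.45
  di <- seq(20, 480, by = 40)
  map <- fit_restitution_spline(data.frame(di = di, apd = a + b * di))
  T <- 500
  di_star <- (T - a) / (1 + b)
  tr <- iterate_map(map, T, DI0 = 100, n_max = 200)
  expect_equal(tr$status, "converged_period1")
  expect_equal(tail(tr$di, 1), di_star, tolerance = 1e-6)
  # |b| > 1: diverging alternation (no convergence to the fixed point)
  b2 <- 1.6
  map2 <- fit_restitution_spline(data.frame(di = di, apd = 50 + b2 * di))
  tr2 <- iterate_map(map2, 500, DI0 = (500 - 50) / (1 + b2) + 1, n_max = 100)
  expect_false(tr2$status == "converged_period1")
})

test_that("the block rule fires immediately when T - F(DI0) < DImin", {
  pts <- data.frame(di = c(50, 150, 300, 450), apd = 400)
  map <- fit_restitution_spline(pts, dimin_block = 25)
  tr <- iterate_map(map, T = 420, DI0 = 200)
  expect_equal(tr$status, "block")
  expect_length(tr$apd, 1)
  expect_error(iterate_map(map, 500, DI0 = 1000), "domain")
})

test_that("second-iterate analysis of a contracting linear map", {
  a <- 150; b <- 0.5
  di <- seq(20, 480, by = 20)
  map <- fit_restitution_spline(data.frame(di = di, apd = a + b * di))
  fp <- second_iterate_fixed_points(map, T = 500)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$di, (500 - a) / (1 + b), tolerance = 1e-4)
  expect_equal(fp$stability, "stable")
  expect_equal(fp$type, "period1")
  expect_equal(fp$slope, b^2, tolerance = 1e-3)
})

test_that("period-1 fixed points are a subset of second-iterate fixed points", {
  pts <- generate_fixture("toy_restitution", amp = 250, width = 30)$points
  map <- fit_restitution_spline(pts)
  for (T in c(520, 600, 680)) {
    G <- function(x) T - map$F(x)
    g2 <- second_iterate_fixed_points(map, T)
    # locate G fixed points by brute bracketing
    xs <- seq(map$domain[1], map$domain[2], length.out = 4000)
    hs <- G(xs) - xs
    for (i in which(hs[-1] * hs[-4000] < 0)) {
      r <- uniroot(function(x) G(x) - x, c(xs[i], xs[i + 1]), tol = 1e-8)$root
      expect_true(min(abs(g2$di - r)) < 1e-3)
    }
  }
})

test_that("a planted period-2 orbit is recovered to 1e-4 ms", {
  fx <- generate_fixture("reverse_engineered_map", T = 650, di_a = 250,
                         di_b = 420)
  map <- fit_restitution_spline(fx$points)
  fp <- second_iterate_fixed_points(map, fx$T)
  for (d in fx$orbit)
    expect_lt(min(abs(fp$di - d)), 1e-4)
  # orbit members are flagged as period-2, not period-1
  hits <- vapply(fx$orbit, function(d) which.min(abs(fp$di - d)), integer(1))
  expect_true(all(fp$type[hits] == "period2-member"))
})

test_that("stability classification agrees with long-run iteration", {
  fx <- generate_fixture("reverse_engineered_map", T = 650)
  map <- fit_restitution_spline(fx$points)
  T <- fx$T
  fp <- second_iterate_fixed_points(map, T)
  set.seed(1)
  for (k in 1:40) {
    di0 <- runif(1, map$domain[1] + 1, map$domain[2] - 1)
    tr <- iterate_map(map, T, di0, n_max = 400)
    if (tr$status %in% c("converged_period1", "period2")) {
      d_end <- tail(tr$di, 1)
      j <- which.min(abs(fp$di - d_end))
      # trajectories land on (near-)stable roots only
      expect_lt(abs(fp$slope[j]), 1 + 1e-6)
    }
  }
})

test_that("linear maps sweep without hysteresis; labels are order-independent", {
  di <- seq(20, 480, by = 40)
  map <- fit_restitution_spline(data.frame(di = di, apd = 150 + 0.4 * di))
  bd <- map_bifurcation_diagram(map, T_range = seq(420, 620, by = 20))
  expect_null(bd$hysteresis)
  up <- bd$data[bd$data$direction == "up", ]
  dn <- bd$data[bd$data$direction == "down", ]
  m <- merge(up, dn, by = "T")
  expect_equal(m$apd.x, m$apd.y, tolerance = 1e-6)

  pd <- phase_diagram(map, T_grid = c(450, 550), DI0_grid = c(50, 200, 400),
                      n_iter = 100)
  expect_true(all(pd == "period1"))
  pd2 <- phase_diagram(map, T_grid = c(550, 450), DI0_grid = c(400, 200, 50),
                       n_iter = 100)
  expect_equal(unname(pd[, "450"]), rev(unname(pd2[, "450"])))
})

test_that("a map exceeding T - DImin over part of its domain shows block", {
  pts <- generate_fixture("toy_restitution", base = 200, amp = 300,
                          di_mid = 300, width = 20)$points
  map <- fit_restitution_spline(pts, dimin_block = 25)
  pd <- phase_diagram(map, T_grid = c(480, 520), DI0_grid = seq(50, 450, 50),
                      n_iter = 100)
  expect_true(any(pd == "block"))
})

test_that("cobweb polylines are consistent with map iteration", {
  fx <- generate_fixture("toy_restitution")
  map <- fit_restitution_spline(fx$points)
  cw <- cobweb_trajectory(map, T = 600, DI0 = 100, n = 1)
  expect_equal(nrow(cw), 3)  # exactly 2 segments
  tr <- iterate_map(map, 600, 100, n_max = 5)
  cw5 <- cobweb_trajectory(map, 600, 100, 5)
  expect_equal(cw5$apd[2 * (1:5)], tr$apd)
  expect_equal(cw5$di[2 * (1:5) + 1], tr$di[-1])
  # fixed-point start degenerates to a single point
  fp <- second_iterate_fixed_points(map, 600)
  st <- fp$di[fp$type == "period1" & fp$stability == "stable"][1]
  if (!is.na(st)) {
    cwf <- cobweb_trajectory(map, 600, st, 3)
    expect_lt(max(dist(cwf)), 1e-3)
  }
})
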