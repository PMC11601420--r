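test_that("the diffusion substep conserves total voltage with no-flux borders", {
  set.seed(2)
  v <- matrix(rnorm(30 * 20, -60, 30), 30, 20)
  v2 <- diffusion_substep(v, DV = 1e-4, dx = 0.015, dt = 0.1)
  expect_equal(sum(v2), sum(v), tolerance = 1e-9)
  # a single depolarized cell relaxes toward its neighbours
  v <- matrix(-80, 11, 11)
  v[6, 6] <- 20
  v2 <- diffusion_substep(v, dt = 0.5)
  expect_lt(v2[6, 6], 20)
  expect_gt(v2[6, 5], -80)
  # stability guard refuses an oversized step
  expect_error(diffusion_substep(v, DV = 1e-3, dx = 0.015, dt = 0.5),
               "unstable")
})

test_that("a spatially uniform deterministic field stays uniform", {
  p <- ead_params()
  run <- run_tissue(p, 4, 4, stim_times = c(0, 400), t_end = 700,
                    probes = cbind(c(1, 2, 4), c(1, 3, 4)), record_dt = 1,
                    snap_dt = 100)
  for (f in seq_along(run$snap_t))
    expect_lt(diff(range(run$snapshots[f, ])), 1e-10)
})

test_that("with DV = 0 every tissue cell reproduces the isolated cell exactly", {
  p <- ead_params()
  md <- ead_mode("stochastic", 4000, 21)
  run <- run_tissue(p, 2, 2, stim_times = c(0, 420), t_end = 840, DV = 0,
                    mode = md, probes = cbind(c(1, 2), c(1, 2)), record_dt = 1)
  # isolated cell with the stream key of grid cell (2,2) (0-based key (1,1))
  iso <- cpp_sim_cell(unclass(p), NULL, c(0, 420), 840, 1, TRUE, 4000L,
                      21, 1, 1, 0, 0, FALSE)
  expect_identical(run$probes$v_1_1, iso$trace$v)
})

test_that("plane-wave conduction velocity is positive and increases with DV", {
  p <- ead_params()
  cv_of <- function(DV) {
    run <- run_tissue(p, 1, 60, stim_times = 0, stim_region = c(1, 1, 1, 5),
                      t_end = 250, DV = DV, record_dt = 1)
    ev <- run$events
    t1 <- ev$time[ev$col == 20 & ev$type == 1][1]
    t2 <- ev$time[ev$col == 50 & ev$type == 1][1]
    expect_false(is.na(t1) || is.na(t2))
    30 * 0.015 / (t2 - t1)  # cm/ms
  }
  cvs <- vapply(c(0.5e-4, 1e-4, 2e-4), cv_of, numeric(1))
  expect_true(all(cvs > 0))
  expect_true(all(diff(cvs) > 0))
})

test_that("a 1-cell grid reduces to the single-cell protocol", {
  p <- ead_params()
  run <- run_tissue(p, 1, 1, stim_times = c(0, 400), t_end = 800, DV = 0,
                    probes = cbind(1, 1), record_dt = 1)
  am <- apd_map(run)
  expect_equal(nrow(am), 2)
  tr <- run_paced(p, 400, 2, mode = mode_det, record_dt = 1, tail_ms = 400)
  ser <- measure_apd(tr)
  # the trace starts at the first stimulus, so the offline measurement can
  # only resolve beats after the first
  ok <- !is.na(ser$apd)
  expect_gt(sum(ok), 0)
  expect_equal(am$apd[ok], ser$apd[ok], tolerance = 1.5)
})

test_that("online tissue APD events agree with offline trace measurement", {
  p <- ead_params()
  run <- run_tissue(p, 1, 8, stim_times = c(0, 430), t_end = 860,
                    probes = cbind(1, 4), record_dt = 0.5)
  am <- apd_map(run)
  a_online <- am$apd[am$row == 1 & am$col == 4]
  tr <- data.frame(t = run$probes$t, v = run$probes$v_0_3)
  ser <- measure_apd(tr, stim_times = c(0, 430))
  expect_equal(a_online, ser$apd, tolerance = 1)
})

test_that("wavebreak flags a gapped front and ignores quiescent or planar fields", {
  nr <- 30; nc <- 30
  planar <- matrix(-80, nr, nc)
  planar[, 1:10] <- 10  # contiguous half-plane front
  gapped <- planar
  gapped[13:18, ] <- -80  # the front is interrupted mid-tissue
  quiet <- matrix(-80, nr, nc)
  mk <- function(vm) {
    list(snap_t = 10, snapshots = matrix(as.vector(t(vm)), 1), nr = nr,
         nc = nc, events = data.frame(row = integer(0), col = integer(0),
                                      type = numeric(0), time = numeric(0)),
         stim_times = 0)
  }
  expect_equal(nrow(detect_block_and_break(mk(gapped))$wavebreak), 1)
  expect_equal(nrow(detect_block_and_break(mk(planar))$wavebreak), 0)
  expect_equal(nrow(detect_block_and_break(mk(quiet))$wavebreak), 0)
})

test_that("block bookkeeping marks unactivated distal beats", {
  ev <- data.frame(row = c(2, 2), col = c(10, 10), type = c(1, 1),
                   time = c(5, 405))
  run <- list(events = ev, snap_t = numeric(0), snapshots = NULL,
              nr = 3, nc = 10, stim_times = c(0, 400, 800))
  bb <- detect_block_and_break(run, distal = c(2, 10))
  expect_equal(bb$block$activated, c(TRUE, TRUE, FALSE))
  expect_length(bb$reentry, 0)
})
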