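#' Run a paced tissue simulation
#'
#' Solves the monodomain cable equation on an `nr x nc` lattice of cells with
#' first-order operator splitting: a reaction substep (the full cell model,
#' adaptive internal timestep) followed by an explicit diffusion substep
#' (5-point Laplacian, no-flux boundaries).  Each cell owns an independent
#' spark stream keyed by `(seed, row, col)`, so results do not depend on grid
#' traversal order.
#'
#' @param params an [ead_params()].
#' @param nr,nc grid dimensions (cells).
#' @param stim_times stimulus onset times (ms).
#' @param stim_region integer vector `c(r0, r1, c0, c1)` (1-based, inclusive)
#'   delimiting the paced rectangle; default the whole grid (uniform pacing).
#' @param t_end total simulated time (ms).
#' @param mode an [ead_mode()].
#' @param DV voltage diffusion coefficient (cm^2/ms, default 1e-4).
#' @param dx lattice spacing (cm, default 0.015).
#' @param probes matrix/data.frame of probe cells (columns `row`, `col`,
#'   1-based) whose voltage is recorded at `record_dt`.
#' @param record_dt probe sampling (ms, default 1).
#' @param snap_dt voltage-field snapshot interval (ms; 0 disables).
#' @param states0 optional initial state: a single cell state (replicated) or
#'   a list of `nr * nc` states from a previous run.
#' @param return_states keep the final per-cell states (for protocol
#'   chaining).
#' @param epoch spark-stream epoch (advance when chaining segments).
#' @return object of class `ead_tissue_run`: `probes` (data.frame), `events`
#'   (per-cell upstroke / -40 mV crossing times), `snapshots` + `snap_t`,
#'   `states`, and the run geometry.
#' @export
run_tissue <- function(params, nr, nc, stim_times, stim_region = NULL,
                       t_end = NULL, mode = ead_mode("deterministic"),
                       DV = 1e-4, dx = 0.015, probes = NULL, record_dt = 1,
                       snap_dt = 0, states0 = NULL, return_states = FALSE,
                       epoch = 0) {
  stim_region <- stim_region %||% c(1, nr, 1, nc)
  stopifnot(length(stim_region) == 4, stim_region[1] >= 1,
            stim_region[2] <= nr, stim_region[3] >= 1, stim_region[4] <= nc)
  t_end <- t_end %||% (max(stim_times) + 600)
  if (is.null(probes)) probes <- cbind(row = ceiling(nr / 2),
                                       col = ceiling(nc / 2))
  probes <- as.matrix(probes)
  stoch <- mode$mode == "stochastic"
  out <- cpp_sim_tissue(unclass(params), nr, nc, states0,
                        as.integer(stim_region - 1), stim_times, t_end,
                        DV, dx,
                        as.integer(probes[, 1] - 1),
                        as.integer(probes[, 2] - 1),
                        record_dt, snap_dt, stoch,
                        if (stoch) mode$Nb else 1L,
                        if (stoch) mode$seed else 0, epoch,
                        return_states, TRUE)
  ev <- out$events
  ev$row <- ev$row + 1
  ev$col <- ev$col + 1
  structure(list(probes = as.data.frame(out$probes), events = ev,
                 snap_t = out$snap_t, snapshots = out$snapshots,
                 states = out$states, nr = nr, nc = nc,
                 stim_times = stim_times, DV = DV, dx = dx,
                 params = params, mode = mode),
            class = "ead_tissue_run")
}

#' @export
print.ead_tissue_run <- function(x, ...) {
  cat("<ead_tissue_run> ", x$nr, "x", x$nc, " cells, ",
      length(x$stim_times), " stimuli, ", nrow(x$events), " events\n",
      sep = "")
  invisible(x)
}

#' Advance a tissue grid by a single splitting step
#'
#' One reaction + diffusion step of length `dt` with no stimulus.  A thin
#' surface over the solver for state-level tests; long protocols should use
#' [run_tissue()].
#'
#' @param states list of `nr * nc` cell states (row-major) or one state to
#'   replicate.
#' @param params an [ead_params()].
#' @param nr,nc grid dimensions.
#' @param dt step (ms).
#' @param DV,dx diffusion coefficient and spacing.
#' @param mode an [ead_mode()].
#' @param epoch spark-stream epoch.
#' @return list of updated per-cell states.
#' @export
step_tissue <- function(states, params, nr, nc, dt = 0.1, DV = 1e-4,
                        dx = 0.015, mode = ead_mode("deterministic"),
                        epoch = 0) {
  p <- unclass(params)
  p$dt_slow <- dt
  p$dt_fast <- dt / 10
  stoch <- mode$mode == "stochastic"
  out <- cpp_sim_tissue(p, nr, nc, states, as.integer(c(0, -1, 0, -1)),
                        numeric(0), dt, DV, dx, integer(0), integer(0),
                        dt, 0, stoch, if (stoch) mode$Nb else 1L,
                        if (stoch) mode$seed else 0, epoch, TRUE, FALSE)
  out$states
}

#' Diffusion substep on a voltage field
#'
#' The explicit 5-point Laplacian update with no-flux boundaries used inside
#' the tissue solver, exposed for conservation and stability checks.
#'
#' @param v voltage matrix (mV).
#' @param DV diffusion coefficient (cm^2/ms).
#' @param dx spacing (cm).
#' @param dt step (ms); refused when `DV dt / dx^2 > 0.25`.
#' @return updated matrix.
#' @export
diffusion_substep <- function(v, DV = 1e-4, dx = 0.015, dt = 0.1) {
  cpp_diffuse(v, DV, dx, dt)
}

#' Per-cell per-beat APD map from tissue events
#'
#' Pairs each cell's upstrokes with the following -40 mV downward crossings
#' (the same threshold rule as [measure_apd()], applied online by the
#' solver).
#'
#' @param run an `ead_tissue_run`.
#' @return data.frame `row`, `col`, `beat`, `up_time`, `apd`, `di` (DI to the
#'   next upstroke; NA for the last beat or censored beats).
#' @export
apd_map <- function(run) {
  ev <- run$events
  out <- list()
  key <- paste(ev$row, ev$col)
  for (k in unique(key)) {
    e <- ev[key == k, ]
    e <- e[order(e$time), ]
    ups <- e$time[e$type == 1]
    if (!length(ups)) next
    dns <- e$time[e$type == 2]
    apd <- rep(NA_real_, length(ups))
    di <- rep(NA_real_, length(ups))
    lim <- c(ups[-1], Inf)
    for (b in seq_along(ups)) {
      d <- dns[dns > ups[b] & dns < lim[b]]
      if (length(d)) {
        apd[b] <- d[1] - ups[b]
        if (b < length(ups)) di[b] <- ups[b + 1] - d[1]
      }
    }
    out[[k]] <- data.frame(row = e$row[1], col = e$col[1],
                           beat = seq_along(ups), up_time = ups,
                           apd = apd, di = di)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Conduction block, wavebreak and reentry diagnostics
#'
#' Scans a tissue run for three kinds of event.  *Block*: a stimulus after
#' which the distal reference cell shows no upstroke before the next
#' stimulus.  *Wavebreak*: a snapshot frame in which the activation front
#' (depolarized cells, V >= -20 mV, adjacent to recovered cells, V <= -60 mV)
#' is discontinuous, i.e. splits into two or more connected components of at
#' least `min_size` cells.  *Reentry*: an upstroke at the distal reference
#' cell more than `reentry_window` ms after the latest stimulus.  Wavebreak
#' detection needs snapshots at roughly >= 1 frame / 10 ms to be reliable; a
#' warning is issued for coarser cadences.
#'
#' @param run an `ead_tissue_run` (snapshots required for wavebreak).
#' @param distal `c(row, col)` of the reference cell (default: mid-row, last
#'   column).
#' @param min_size minimum front component size (cells, default 3).
#' @param reentry_window ms after a stimulus within which activation is
#'   attributed to pacing (default 250).
#' @return list with `block` (data.frame per stimulus: `stim_time`,
#'   `activated`), `wavebreak` (data.frame per flagged frame: `time`,
#'   `n_components`), `reentry` (times of non-stimulated distal
#'   activations).
#' @export
detect_block_and_break <- function(run, distal = NULL, min_size = 3,
                                   reentry_window = 250) {
  distal <- distal %||% c(ceiling(run$nr / 2), run$nc)
  ev <- run$events
  ups <- ev$time[ev$row == distal[1] & ev$col == distal[2] & ev$type == 1]
  st <- run$stim_times
  lim <- c(st[-1], Inf)
  block <- data.frame(stim_time = st,
                      activated = vapply(seq_along(st), function(k)
                        any(ups >= st[k] & ups < lim[k]), logical(1)))
  wb <- data.frame(time = numeric(0), n_components = integer(0))
  if (length(run$snap_t)) {
    if (length(run$snap_t) > 1 && min(diff(run$snap_t)) > 10 + 1e-9)
      warning("snapshot cadence coarser than 10 ms; wavebreak detection unreliable")
    for (f in seq_along(run$snap_t)) {
      vm <- matrix(run$snapshots[f, ], run$nr, run$nc, byrow = TRUE)
      ncomp <- front_components(vm, min_size)
      if (ncomp >= 2)
        wb <- rbind(wb, data.frame(time = run$snap_t[f],
                                   n_components = ncomp))
    }
  }
  reentry <- ups[vapply(ups, function(u) {
    prev <- st[st <= u]
    !length(prev) || u - max(prev) > reentry_window
  }, logical(1))]
  list(block = block, wavebreak = wb, reentry = reentry)
}

# connected components (4-neighbour) of the activation front:
# depolarized cells adjacent to recovered tissue
front_components <- function(vm, min_size = 3, v_act = -20, v_rec = -60) {
  nr <- nrow(vm)
  nc <- ncol(vm)
  act <- vm >= v_act
  rec <- vm <= v_rec
  if (!any(act) || !any(rec)) return(0L)
  near_rec <- matrix(FALSE, nr, nc)
  near_rec[-1, ] <- near_rec[-1, ] | rec[-nr, ]
  near_rec[-nr, ] <- near_rec[-nr, ] | rec[-1, ]
  near_rec[, -1] <- near_rec[, -1] | rec[, -nc]
  near_rec[, -nc] <- near_rec[, -nc] | rec[, -1]
  front <- act & near_rec
  if (!any(front)) return(0L)
  # flood fill
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  sizes <- integer(0)
  for (i in which(front)) {
    if (lab[i] > 0) next
    cur <- cur + 1L
    stack <- i
    lab[i] <- cur
    sz <- 0L
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      sz <- sz + 1L
      r <- (j - 1) %% nr + 1
      cc <- (j - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        j2 <- (c2 - 1) * nr + r2
        if (front[j2] && lab[j2] == 0) {
          lab[j2] <- cur
          stack <- c(stack, j2)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sum(sizes >= min_size)
}

#' Tissue S1S2 restitution and conduction-block threshold
#'
#' On a deterministic tissue strip, paces a proximal region to steady state
#' at `S1`, then for each S2 restarts from the stored state, delivers the
#' final two stimuli `S2` ms apart, and measures the APD and preceding DI at
#' the distal cell.  An S2 whose excitation never reaches the distal cell is
#' recorded as a conduction-block point.
#'
#' @param params an [ead_params()].
#' @param nr,nc strip dimensions (default 3 x 60 cells).
#' @param stim_cols columns of the paced strip (default 1:10).
#' @param S1 conditioning cycle length (ms).
#' @param s2_list S2 intervals (ms).
#' @param beats_S1 conditioning beats (default 20; the strip reaches its
#'   periodic state quickly under deterministic dynamics).
#' @param distal `c(row, col)` of the measurement cell (default middle row,
#'   last column).
#' @param DV,dx cable parameters.
#' @param tail_ms time simulated after the S2 stimulus.
#' @return data.frame of class `restitution_points`: `s2`, `di`, `apd`,
#'   `blocked`.
#' @export
tissue_s1s2 <- function(params, nr = 3, nc = 60, stim_cols = 1:10, S1 = 500,
                        s2_list, beats_S1 = 20, distal = NULL, DV = 1e-4,
                        dx = 0.015, tail_ms = 900) {
  distal <- distal %||% c(ceiling(nr / 2), nc)
  region <- c(1, nr, min(stim_cols), max(stim_cols))
  cond <- run_tissue(params, nr, nc, stim_times = (0:(beats_S1 - 2)) * S1,
                     stim_region = region, t_end = (beats_S1 - 1) * S1,
                     DV = DV, dx = dx, return_states = TRUE)
  base <- cond$states
  rows <- lapply(seq_along(s2_list), function(k) {
    s2 <- s2_list[k]
    tr <- run_tissue(params, nr, nc, stim_times = c(0, s2),
                     stim_region = region, t_end = s2 + tail_ms, DV = DV,
                     dx = dx, states0 = base, epoch = 1000 + k)
    ev <- tr$events
    e <- ev[ev$row == distal[1] & ev$col == distal[2], ]
    e <- e[order(e$time), ]
    ups <- e$time[e$type == 1]
    dns <- e$time[e$type == 2]
    # need the S1 beat (from stim at 0) and the S2 beat; for a blocked S2
    # the diastolic interval is reported as the would-be arrival time of the
    # S2 front (S1 conduction delay) minus the distal repolarization time
    if (length(ups) >= 1) {
      delay <- ups[1]
      d1_all <- dns[dns > ups[1]]
      di_virtual <- if (length(d1_all)) s2 + delay - d1_all[1] else NA_real_
    } else di_virtual <- NA_real_
    if (length(ups) < 2)
      return(data.frame(s2 = s2, di = di_virtual, apd = NA_real_,
                        blocked = TRUE))
    d1 <- dns[dns > ups[1] & dns < ups[2]]
    d2 <- dns[dns > ups[2]]
    if (!length(d1) || !length(d2))
      return(data.frame(s2 = s2, di = di_virtual, apd = NA_real_,
                        blocked = TRUE))
    data.frame(s2 = s2, di = ups[2] - d1[1], apd = d2[1] - ups[2],
               blocked = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("restitution_points", "data.frame"), S1 = S1)
}
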