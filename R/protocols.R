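#' Measure per-beat APD and DI from a voltage trace
#'
#' An upstroke is an upward crossing of -20 mV within 10 ms of a stimulus
#' (plateau oscillations from EADs never re-cross from below, so they are not
#' counted as new upstrokes).  The APD ends at the first downward crossing of
#' the repolarization threshold after the upstroke: either a fixed -40 mV
#' (`threshold_mode = "fixed_mV"`, the convention used for EAD statistics) or
#' 90% repolarization toward the pre-stimulus baseline
#' (`threshold_mode = "percent_repol"`).  Crossing times are linearly
#' interpolated between samples.  A beat whose voltage never re-crosses the
#' threshold before the next upstroke is censored: its APD is set to the full
#' interval and flagged.  `DI` is the time from the threshold crossing to the
#' next upstroke.
#'
#' @param trace an `ead_trace` or a data.frame with columns `t`, `v` (ms, mV);
#'   sampling must be at most 1 ms.
#' @param threshold_mode `"fixed_mV"` (default, -40 mV) or `"percent_repol"`
#'   (90%).
#' @param stim_times stimulus times (taken from the trace object when
#'   omitted).
#' @param threshold threshold value: mV for `"fixed_mV"` (default -40),
#'   percent repolarization for `"percent_repol"` (default 90).
#' @return data.frame of class `apd_series` with columns `beat`, `stim_time`,
#'   `up_time`, `apd`, `di`, `captured`, `censored`, plus attributes
#'   `threshold_mode`, `threshold`.
#' @export
measure_apd <- function(trace, threshold_mode = c("fixed_mV", "percent_repol"),
                        stim_times = NULL, threshold = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (inherits(trace, "ead_trace")) {
    stim_times <- stim_times %||% trace$stim_times
    trace <- trace$trace
  }
  if (is.null(stim_times)) stop("stim_times required for a bare trace")
  t <- trace$t
  v <- trace$v
  if (length(t) > 1 && max(diff(t)) > 1 + 1e-9)
    warning("trace sampling coarser than 1 ms; APD interpolation degraded")
  thr <- threshold %||% if (threshold_mode == "fixed_mV") -40 else 90
  n <- length(stim_times)
  res <- data.frame(beat = seq_len(n), stim_time = stim_times,
                    up_time = NA_real_, apd = NA_real_, di = NA_real_,
                    captured = FALSE, censored = FALSE)
  cross_down <- function(i0, i1, level) {
    # first downward crossing of `level` in sample index range (i0, i1]
    idx <- which(v[i0:(i1 - 1)] > level & v[(i0 + 1):i1] <= level)
    if (!length(idx)) return(NA_real_)
    i <- i0 + idx[1] - 1
    t[i] + (v[i] - level) / (v[i] - v[i + 1]) * (t[i + 1] - t[i])
  }
  up_of <- function(s, s_next) {
    lo <- max(findInterval(s, t) - 1, 1)
    hi <- min(max(findInterval(min(s + 10, s_next), t), 2), length(t))
    if (hi <= lo) return(NA_real_)
    idx <- which(v[lo:(hi - 1)] < -20 & v[(lo + 1):hi] >= -20)
    if (!length(idx)) return(NA_real_)
    i <- lo + idx[1] - 1
    t[i] + (-20 - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  ends <- c(stim_times[-1], t[length(t)])
  for (b in seq_len(n)) {
    up <- up_of(stim_times[b], ends[b])
    if (is.na(up)) next  # capture failure
    res$captured[b] <- TRUE
    res$up_time[b] <- up
    level <- thr
    if (threshold_mode == "percent_repol") {
      vrest <- v[max(findInterval(stim_times[b], t), 1)]
      i_up <- findInterval(up, t)
      i_end <- findInterval(ends[b], t)
      vmax <- max(v[i_up:max(i_up, i_end)])
      level <- vmax - (thr / 100) * (vmax - vrest)
    }
    i_up <- findInterval(up, t) + 1
    i_end <- max(findInterval(ends[b], t), i_up + 1)
    dn <- cross_down(i_up, min(i_end, length(t)), level)
    if (is.na(dn)) {
      res$censored[b] <- TRUE
      res$apd[b] <- ends[b] - up
    } else {
      res$apd[b] <- dn - up
      if (b < n) {
        up_next <- up_of(stim_times[b + 1], ends[b + 1])
        if (!is.na(up_next)) res$di[b] <- up_next - dn
      }
    }
  }
  structure(res, class = c("apd_series", "data.frame"),
            threshold_mode = threshold_mode, threshold = thr)
}

#' Mean, standard deviation and coefficient of variability of an APD series
#'
#' Censored and non-captured beats are excluded (but counted).  The standard
#' deviation uses the population convention (divisor `n`), and
#' `cv = 100 * sigma / mean` is in percent.
#'
#' @param series an [measure_apd()] result (or any data.frame with `apd`,
#'   `captured`, `censored`).
#' @return list with `mean`, `sigma`, `cv`, `n`, `n_censored`, `n_failed`.
#' @export
apd_statistics <- function(series) {
  ok <- series$captured & !series$censored & !is.na(series$apd)
  x <- series$apd[ok]
  if (length(x) < 2)
    stop("undefined statistics: fewer than 2 uncensored captured beats")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  list(mean = m, sigma = s, cv = 100 * s / m, n = length(x),
       n_censored = sum(series$censored), n_failed = sum(!series$captured))
}

#' Detect an EAD notch on each beat
#'
#' A beat carries an EAD when, between the upstroke and final repolarization,
#' the voltage exhibits a local minimum followed by a local maximum with both
#' extrema above -40 mV and a rise of at least `prominence` mV (a "notch" in
#' the plateau).
#'
#' @param trace an `ead_trace` or data.frame with `t`, `v`.
#' @param series the matching [measure_apd()] result (computed when omitted).
#' @param stim_times stimulus times for a bare trace.
#' @param prominence minimum notch depth/rise (mV, default 2).
#' @return logical vector, one element per beat (NA for failed captures).
#' @export
detect_ead <- function(trace, series = NULL, stim_times = NULL,
                       prominence = 2) {
  if (inherits(trace, "ead_trace")) {
    stim_times <- stim_times %||% trace$stim_times
    tr <- trace$trace
  } else tr <- trace
  if (is.null(series)) series <- measure_apd(tr, stim_times = stim_times)
  t <- tr$t
  v <- tr$v
  n <- nrow(series)
  out <- rep(NA, n)
  ends <- c(series$stim_time[-1], t[length(t)])
  for (b in seq_len(n)) {
    if (!series$captured[b]) next
    i0 <- findInterval(series$up_time[b], t) + 1
    fin <- series$up_time[b] + series$apd[b]
    i1 <- min(findInterval(fin, t) + 1, length(t))
    out[b] <- FALSE
    if (i1 - i0 < 5) next
    seg <- v[i0:i1]
    dv <- diff(seg)
    sgn <- sign(dv)
    sgn[sgn == 0] <- 1
    turn <- diff(sgn)
    mins <- which(turn > 0) + 1
    maxs <- which(turn < 0) + 1
    for (im in mins) {
      if (seg[im] <= -40) next
      later_max <- maxs[maxs > im]
      if (!length(later_max)) next
      if (max(seg[later_max]) - seg[im] >= prominence &&
          max(seg[later_max]) > -40) {
        out[b] <- TRUE
        break
      }
    }
  }
  out
}

#' Dynamic pacing sweep with carried state
#'
#' Paces `beats_per_CL` beats at each cycle length in turn, carrying the full
#' cell state (and spark stream) across CL changes with no reset, and records
#' the APD of the last `record_last` beats per CL.  With
#' `direction = "up_then_down"` the CL list is traversed forward and then
#' backward (skipping the duplicated turning point), which exposes hysteresis
#' of the alternans transition.
#'
#' @param params an [ead_params()].
#' @param CLs ordered cycle lengths (ms).
#' @param beats_per_CL beats paced at each CL (default 200).
#' @param record_last beats recorded at each CL (default 50).
#' @param direction `"up"`, `"down"`, or `"up_then_down"`.
#' @param mode an [ead_mode()].
#' @param state0 optional starting state.
#' @return data.frame of class `ead_bifurcation`: `direction`, `CL`, `beat`,
#'   `apd`, `censored`, `ead`.
#' @export
dynamic_pacing_sweep <- function(params, CLs, beats_per_CL = 200,
                                 record_last = 50,
                                 direction = c("up", "down", "up_then_down"),
                                 mode = ead_mode("deterministic"),
                                 state0 = NULL) {
  direction <- match.arg(direction)
  stopifnot(record_last <= beats_per_CL)
  plan <- switch(direction,
    up = data.frame(dir = "up", CL = CLs),
    down = data.frame(dir = "down", CL = rev(CLs)),
    up_then_down = data.frame(dir = rep(c("up", "down"),
                                        c(length(CLs), length(CLs) - 1)),
                              CL = c(CLs, rev(CLs)[-1])))
  state <- state0
  rows <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    CL <- plan$CL[k]
    tr <- run_paced(params, CL, beats_per_CL, mode = mode, state0 = state,
                    record_from_beat = beats_per_CL - record_last + 1,
                    tail_ms = CL, epoch = k - 1)
    state <- tr$state
    keep <- seq(beats_per_CL - record_last + 1, beats_per_CL)
    ser <- measure_apd(tr$trace, stim_times = tr$stim_times[keep])
    ead <- detect_ead(tr$trace, ser, stim_times = tr$stim_times[keep])
    rows[[k]] <- data.frame(direction = plan$dir[k], CL = CL,
                            beat = keep, apd = ser$apd,
                            captured = ser$captured,
                            censored = ser$censored, ead = ead)
  }
  structure(do.call(rbind, rows), class = c("ead_bifurcation", "data.frame"))
}

#' S1S2 restitution protocol (single cell)
#'
#' Paces `beats_S1` beats at cycle length `S1`, stores the steady state just
#' before the last S1 beat, and then for each `S2` restarts from that stored
#' state and delivers the final two stimuli `S2` ms apart.  Each trial is
#' independent given the stored state.  Returns, per S2, the APD of the final
#' beat and the diastolic interval preceding it.
#'
#' @param params an [ead_params()].
#' @param S1 conditioning cycle length (ms).
#' @param s2_list S2 coupling intervals (ms).
#' @param beats_S1 conditioning beats (default 50).
#' @param mode an [ead_mode()] (deterministic recommended for map fitting).
#' @param tail_ms time simulated after the S2 stimulus (default 900 ms, long
#'   enough for EAD-prolonged APs to repolarize).
#' @return data.frame of class `restitution_points`: `s2`, `di`, `apd`,
#'   `blocked`.
#' @export
s1s2_restitution <- function(params, S1, s2_list, beats_S1 = 50,
                             mode = ead_mode("deterministic"), tail_ms = 900) {
  stoch <- mode$mode == "stochastic"
  # Store the steady state just before the final S1 beat.  When the S1
  # steady state is an alternans, pick the conditioning parity whose next
  # beat captures and repolarizes quickly, so the pre-S2 diastolic interval
  # is well defined over the widest S2 range.
  probe <- function(n_cond) {
    cond <- run_paced(params, S1, n_cond, mode = mode,
                      record_from_beat = max(n_cond, 1), tail_ms = S1)
    out <- cpp_sim_cell(unclass(params), cond$state, 5, S1 + 600, 0.5,
                        stoch, if (stoch) mode$Nb else 1L,
                        if (stoch) mode$seed else 0, 0, 0, 999, 0, FALSE)
    ser <- measure_apd(as.data.frame(out$trace), stim_times = 5)
    list(state = cond$state,
         apd1 = if (ser$captured[1] && !ser$censored[1]) ser$apd[1] else Inf)
  }
  p1 <- probe(beats_S1 - 1)
  base <- p1$state
  if (!is.finite(p1$apd1)) {
    p2 <- probe(beats_S1)
    if (is.finite(p2$apd1)) base <- p2$state
  }
  rows <- lapply(seq_along(s2_list), function(k) {
    s2 <- s2_list[k]
    out <- cpp_sim_cell(unclass(params), base, 5 + c(0, s2), s2 + tail_ms,
                        0.5, stoch, if (stoch) mode$Nb else 1L,
                        if (stoch) mode$seed else 0, 0, 0, 1000 + k, 0, FALSE)
    ser <- measure_apd(as.data.frame(out$trace), stim_times = 5 + c(0, s2))
    if (!ser$captured[2] || is.na(ser$di[1]))
      return(data.frame(s2 = s2, di = NA_real_, apd = NA_real_,
                        blocked = TRUE))
    data.frame(s2 = s2, di = ser$di[1], apd = ser$apd[2],
               blocked = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("restitution_points", "data.frame"), S1 = S1)
}

#' Electrotonic length scale
#'
#' The distance over which gap-junction coupling averages voltage during one
#' pacing period: `l = sqrt(DV * T)`.
#'
#' @param DV voltage diffusion coefficient (cm^2/ms).
#' @param T pacing period (ms).
#' @return length (cm).
#' @examples
#' electrotonic_length(1e-4, 500)  # ~0.22 cm
#' @export
electrotonic_length <- function(DV, T) {
  stopifnot(DV >= 0, T >= 0)
  sqrt(DV * T)
}
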