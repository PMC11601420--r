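#' Calibrate free phenomenological constants against printed targets
#'
#' The model's Ca-cycling and L-type constants are phenomenological; this
#' routine fixes a chosen subset by cyclic coordinate descent against
#' single-cell targets: steady-state mean APD90 and its standard deviation at
#' a reference cycle length with `Nb` junctional clusters (stochastic run),
#' and optionally the EAD-onset cycle length of the reduced-inactivation
#' model (deterministic sweep).  The search is deterministic given the seed.
#'
#' The objective is a weighted sum of squared relative residuals.  Each
#' coordinate pass evaluates a symmetric multiplicative perturbation of one
#' parameter and keeps the best of the three candidates; the step factor
#' shrinks between sweeps.
#'
#' @param targets list with elements `apd90_mean` (ms), `apd90_sigma` (ms),
#'   and optionally `ead_onset_cl` (ms) and `cv` (percent).
#' @param free_params named list of starting values for the parameters being
#'   searched (names must exist in [ead_params()]).
#' @param params base parameter set the free parameters are applied to.
#' @param CL reference cycle length (ms, default 500).
#' @param Nb cluster count for the stochastic runs (default 4000).
#' @param n_beats beats per stochastic evaluation (default 300; discards
#'   `discard`).
#' @param discard transient beats discarded (default 30).
#' @param n_sweeps coordinate-descent sweeps (default 3).
#' @param step initial multiplicative step (default 1.25).
#' @param seed stochastic-evaluation seed.
#' @param weights named weights for the residual terms.
#' @param verbose print per-evaluation progress.
#' @return list of class `ead_calibration`: `params` (full calibrated set),
#'   `free` (final free-parameter values), `residuals`, `objective`,
#'   `history`.
#' @export
calibrate <- function(targets, free_params, params = ead_params(),
                      CL = 500, Nb = 4000, n_beats = 300, discard = 30,
                      n_sweeps = 3, step = 1.25, seed = 1,
                      weights = c(apd90_mean = 1, apd90_sigma = 1,
                                  ead_onset_cl = 1),
                      verbose = FALSE) {
  stopifnot(all(names(free_params) %in% names(params)))
  evalobj <- function(fp) {
    p <- modifyList(params, as.list(fp))
    class(p) <- class(params)
    res <- c()
    tr <- run_paced(p, CL, n_beats, mode = ead_mode("stochastic", Nb, seed),
                    record_dt = 1, record_from_beat = discard + 1)
    ser <- measure_apd(tr, threshold_mode = "percent_repol",
                       stim_times = tr$stim_times[tr$stim_times >= discard * CL])
    st <- tryCatch(apd_statistics(ser), error = function(e) NULL)
    if (is.null(st)) return(list(obj = Inf, res = c(fail = Inf)))
    if (!is.null(targets$apd90_mean))
      res["apd90_mean"] <- (st$mean - targets$apd90_mean) / targets$apd90_mean
    if (!is.null(targets$apd90_sigma))
      res["apd90_sigma"] <- (st$sigma - targets$apd90_sigma) / targets$apd90_sigma
    if (!is.null(targets$cv))
      res["cv"] <- (st$cv - targets$cv) / targets$cv
    if (!is.null(targets$ead_onset_cl)) {
      pe <- modifyList(p, list(aca = 0.09))
      class(pe) <- class(p)
      on <- ead_onset_cl(pe, CLs = seq(440, 560, by = 20), beats_per_CL = 40,
                         record_last = 10)
      res["ead_onset_cl"] <- if (is.na(on)) 1
        else (on - targets$ead_onset_cl) / targets$ead_onset_cl
    }
    w <- weights[names(res)]
    w[is.na(w)] <- 1
    list(obj = sum(w * res^2), res = res)
  }
  fp <- unlist(free_params)
  cur <- evalobj(fp)
  hist <- list(data.frame(sweep = 0, t(fp), objective = cur$obj))
  s <- step
  for (sw in seq_len(n_sweeps)) {
    for (nm in names(fp)) {
      for (cand in c(fp[[nm]] * s, fp[[nm]] / s)) {
        fp2 <- fp
        fp2[[nm]] <- cand
        alt <- evalobj(fp2)
        if (alt$obj < cur$obj) {
          fp <- fp2
          cur <- alt
        }
      }
      if (verbose)
        message(sprintf("sweep %d %s=%.4g obj=%.4g", sw, nm, fp[[nm]],
                        cur$obj))
    }
    hist[[length(hist) + 1]] <-
      data.frame(sweep = sw, t(fp), objective = cur$obj)
    s <- 1 + (s - 1) / 2
  }
  out <- modifyList(params, as.list(fp))
  class(out) <- class(params)
  structure(list(params = out, free = as.list(fp), residuals = cur$res,
                 objective = cur$obj, history = do.call(rbind, hist)),
            class = "ead_calibration")
}

#' @export
print.ead_calibration <- function(x, ...) {
  cat("<ead_calibration> objective ", signif(x$objective, 4), "\n", sep = "")
  print(unlist(x$free))
  cat("residuals (relative):\n")
  print(round(x$residuals, 4))
  invisible(x)
}

#' Smallest cycle length with EADs in a dynamic sweep
#'
#' Runs [dynamic_pacing_sweep()] upward over `CLs` on the deterministic model
#' and returns the smallest CL at which the per-beat EAD-notch detector fires
#' on any recorded beat (NA when none does).
#'
#' @param params an [ead_params()] (use the reduced-inactivation set to see
#'   an onset).
#' @param CLs ordered cycle lengths (ms).
#' @param beats_per_CL,record_last sweep schedule.
#' @param mode an [ead_mode()].
#' @return onset CL (ms) or NA.
#' @export
ead_onset_cl <- function(params, CLs = seq(440, 552, by = 4),
                         beats_per_CL = 200, record_last = 50,
                         mode = ead_mode("deterministic")) {
  bif <- dynamic_pacing_sweep(params, CLs, beats_per_CL, record_last,
                              direction = "up", mode = mode)
  pos <- bif$CL[!is.na(bif$ead) & bif$ead]
  if (!length(pos)) return(NA_real_)
  min(pos)
}
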