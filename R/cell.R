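#' All membrane currents at a given cell state
#'
#' Evaluates the rabbit ventricular current set (INa, IKr, IKs, IK1, Ito,
#' INaK, INaCa) together with the Markov L-type current, and their signed sum
#' `iion`.  Also returns the molar Ca fluxes (`jca`, `jnaca`) the Ca
#' subsystem receives from the membrane.
#'
#' @param state a cell state list as returned by [cell_state()] or a
#'   simulation.
#' @param params an [ead_params()].
#' @return named list of current densities (uA/uF) plus `iion`, `jca`,
#'   `jnaca`.
#' @export
total_ion_current <- function(state, params) {
  cpp_ionic_currents(state, unclass(params))
}

#' Advance a single cell by one (or more) timesteps
#'
#' One reaction step of the full model with no stimulus, in the fixed update
#' order gating -> L-type -> sparks -> Ca -> currents -> voltage.  Mostly a
#' testing/inspection surface; long runs should use [run_paced()].
#'
#' @param state cell state list.
#' @param dt timestep (ms), in the supported range 0.01-0.1.
#' @param mode an [ead_mode()].
#' @param t_end total time to advance (default one step).
#' @param epoch stream epoch for the stochastic spark draws.
#' @return list with `state` (final state) and `trace`.
#' @export
step_cell <- function(state, dt, mode = ead_mode("deterministic"),
                      t_end = dt, epoch = 0) {
  stopifnot(dt >= 0.001, dt <= 0.1)
  if (t_end == 0) return(list(state = state, trace = NULL))
  p <- ead_params()
  step_cell_with(state, dt, p, mode, t_end, epoch)
}

# internal: step with explicit params
step_cell_with <- function(state, dt, params, mode, t_end, epoch = 0) {
  p <- unclass(params)
  p$dt_slow <- dt
  p$dt_fast <- dt / 10
  out <- cpp_sim_cell(p, state, numeric(0), t_end, dt,
                      mode$mode == "stochastic",
                      if (mode$mode == "stochastic") mode$Nb else 1L,
                      if (mode$mode == "stochastic") mode$seed else 0,
                      0, 0, epoch, 0, TRUE)
  out
}

#' Pace a single cell
#'
#' Delivers `n_beats` stimuli at fixed cycle length `CL` and records the
#' voltage (and optionally the Ca/spark trajectory) at `record_dt` sampling.
#'
#' @param params an [ead_params()].
#' @param CL pacing cycle length (ms); must exceed the stimulus duration.
#' @param n_beats number of stimuli.
#' @param mode an [ead_mode()].
#' @param state0 optional initial state (default [cell_state()]).
#' @param record_dt trace sampling interval (ms, default 0.5).
#' @param record_from_beat first beat (1-based) whose trace is kept; earlier
#'   beats are simulated but not recorded.  Default 1 (keep all).
#' @param record_ca record Ca compartments and spark fraction as well.
#' @param tail_ms extra quiescent time simulated after the final beat so its
#'   repolarization is captured (default one full `CL`).
#' @param epoch stream epoch, advanced by protocol drivers that chain
#'   segments.
#' @return list of class `ead_trace`: `trace` (data.frame with `t`, `v`, ...),
#'   `stim_times`, `state` (final), `params`, `mode`.
#' @examples
#' \donttest{
#' tr <- run_paced(ead_params(), CL = 500, n_beats = 2,
#'                 mode = ead_mode("deterministic"))
#' range(tr$trace$v)
#' }
#' @export
run_paced <- function(params, CL, n_beats, mode = ead_mode(), state0 = NULL,
                      record_dt = 0.5, record_from_beat = 1,
                      record_ca = FALSE, tail_ms = CL, epoch = 0) {
  stopifnot(CL > params$stim_dur, n_beats >= 0)
  if (n_beats == 0) {
    return(structure(list(trace = data.frame(t = numeric(0), v = numeric(0)),
                          stim_times = numeric(0), state = state0 %||% cell_state(),
                          params = params, mode = mode),
                     class = "ead_trace"))
  }
  stim <- (seq_len(n_beats) - 1) * CL
  t_end <- (n_beats - 1) * CL + tail_ms
  rec0 <- if (record_from_beat > 1) (record_from_beat - 1) * CL else 0
  stoch <- mode$mode == "stochastic"
  out <- cpp_sim_cell(unclass(params), state0, stim, t_end, record_dt, stoch,
                      if (stoch) mode$Nb else 1L, if (stoch) mode$seed else 0,
                      0, 0, epoch, rec0, record_ca)
  tr <- as.data.frame(out$trace)
  structure(list(trace = tr, stim_times = stim, state = out$state,
                 params = params, mode = mode),
            class = "ead_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ead_trace <- function(x, ...) {
  cat("<ead_trace> ", length(x$stim_times), " beats, ",
      nrow(x$trace), " samples, mode ", x$mode$mode, "\n", sep = "")
  invisible(x)
}

#' Export a paced trace as CSV
#'
#' Columns: `time_ms`, `v_mV`, and when recorded `cb`, `ci`, `csrb`, `csri`,
#' `pb`, `nb`.
#'
#' @param x an `ead_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  tr <- x$trace
  names(tr)[names(tr) == "t"] <- "time_ms"
  names(tr)[names(tr) == "v"] <- "v_mV"
  write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
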