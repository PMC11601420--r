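#' Spark population state
#'
#' Bookkeeping for the junctional Ca-spark population: `nb` clusters currently
#' sparking out of `Nb` total, with spark fraction `pb = nb/Nb`.
#'
#' @param nb number of sparking clusters (integer, `0 <= nb <= Nb`).
#' @param Nb total number of junctional clusters (positive integer).
#' @return list of class `spark_state`.
#' @export
spark_state <- function(nb = 0, Nb = 4000) {
  stopifnot(Nb >= 1, Nb == round(Nb), nb == round(nb), nb >= 0, nb <= Nb)
  structure(list(nb = as.integer(nb), Nb = as.integer(Nb), pb = nb / Nb),
            class = "spark_state")
}

#' Spark recruitment/extinction rates
#'
#' @param alpha_b recruitment rate per non-sparking cluster (1/ms, `>= 0`).
#' @param beta_b extinction rate per sparking cluster (1/ms, `> 0`).
#' @return list of class `spark_rates`.
#' @export
spark_rates <- function(alpha_b, beta_b) {
  stopifnot(alpha_b >= 0, beta_b > 0)
  structure(list(alpha_b = alpha_b, beta_b = beta_b), class = "spark_rates")
}

#' One stochastic birth-death step of the spark population
#'
#' The spark count evolves as `nb' = nb + B(Nb - nb, alpha_b dt) -
#' B(nb, beta_b dt)` where `B(n, p)` is a binomial draw: every quiescent
#' cluster is recruited independently with probability `alpha_b dt` and every
#' active spark extinguishes with probability `beta_b dt`.  The result is
#' guaranteed to stay in `[0, Nb]` by construction.
#'
#' Draws come from a dedicated counter-based stream keyed by
#' `(seed, key, epoch)`, so trajectories are reproducible and independent of
#' R's global RNG.
#'
#' @param state a [spark_state()].
#' @param rates a [spark_rates()].
#' @param dt timestep (ms, `> 0`).
#' @param seed,key,epoch stream key; successive calls within one trajectory
#'   should advance `epoch` (or use [spark_trajectory()] which handles it).
#' @param subdivide if `TRUE` (default) a step whose success probability would
#'   exceed 1 is internally subdivided, preserving the mean rates; if `FALSE`
#'   such a step is an error.
#' @return updated `spark_state`.
#' @export
step_spark_counts_stochastic <- function(state, rates, dt, seed = 1, key = 0,
                                         epoch = 0, subdivide = TRUE) {
  stopifnot(inherits(state, "spark_state"), inherits(rates, "spark_rates"))
  if (dt <= 0) stop("invalid argument: dt must be positive")
  if (!subdivide && (rates$alpha_b * dt > 1 || rates$beta_b * dt > 1))
    stop("timestep too large for rates: success probability exceeds 1")
  traj <- cpp_spark_trajectory(state$nb, state$Nb, rates$alpha_b, rates$beta_b,
                               dt, seed, key, 0, epoch)
  spark_state(traj[2], state$Nb)
}

#' Stochastic spark-count trajectory
#'
#' Runs `n_steps` birth-death steps (or one step per element of a prescribed
#' `alpha_b`/`beta_b` time course) on a single reproducible stream.
#'
#' @inheritParams step_spark_counts_stochastic
#' @param n_steps number of steps when rates are scalar.
#' @return integer vector of length `n_steps + 1` (including the initial
#'   count).
#' @export
spark_trajectory <- function(state, rates, dt, n_steps = NULL, seed = 1,
                             key = 0, epoch = 0) {
  stopifnot(inherits(state, "spark_state"))
  a <- rates$alpha_b
  b <- rates$beta_b
  if (length(a) == 1 && length(b) == 1) {
    stopifnot(!is.null(n_steps))
    a <- rep(a, n_steps)
  }
  if (dt <= 0) stop("invalid argument: dt must be positive")
  cpp_spark_trajectory(state$nb, state$Nb, a, b, dt, seed, key, 0, epoch)
}

#' One deterministic step of the spark fraction
#'
#' Integrates the mean-field limit `dpb/dt = alpha_b (1 - pb) - beta_b pb`
#' (the infinite-cluster limit of the birth-death process) with an explicit
#' Euler step, matching the in-simulator update.
#'
#' @param pb spark fraction in `[0, 1]`.
#' @param rates a [spark_rates()].
#' @param dt timestep (ms).
#' @return updated spark fraction, clamped to `[0, 1]`.
#' @export
step_spark_fraction_deterministic <- function(pb, rates, dt) {
  if (pb < 0 || pb > 1) stop("invalid state: pb must be in [0, 1]")
  if (dt < 0) stop("invalid argument: dt must be nonnegative")
  out <- pb + dt * (rates$alpha_b * (1 - pb) - rates$beta_b * pb)
  min(max(out, 0), 1)
}

#' Spark recruitment rate from the L-type open fraction and SR load
#'
#' `alpha_b = alpha0 * lcc_open_fraction * S(csrb)` where the load factor
#' `S(c) = c^2 / (c^2 + ksr^2)` is a Hill sigmoid: recruitment requires both
#' an L-type trigger and releasable SR Ca.
#'
#' @param lcc_open_fraction spark-off open-state occupancy in `[0, 1]`.
#' @param csrb junctional SR Ca (uM).
#' @param params an [ead_params()] (uses `alpha0`, `ksr`).
#' @return recruitment rate (1/ms).
#' @export
spark_recruitment_rate <- function(lcc_open_fraction, csrb, params) {
  stopifnot(lcc_open_fraction >= 0, csrb >= 0)
  s <- csrb^2 / (csrb^2 + params$ksr^2)
  params$alpha0 * lcc_open_fraction * s
}
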