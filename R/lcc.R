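#' Ca-dependent inactivation factor of the L-type channel
#'
#' `FCa(cb) = 1 / (1 + (cth/cb)^2)`: a Hill sigmoid rising from 0 at low
#' junctional Ca to 1 far above the inactivation threshold `cth`.  Channels
#' inside an active spark domain face ~100 uM local Ca, far above any
#' physiological `cth`, and use `FCa = 1` exactly.
#'
#' @param cb junctional cytosolic Ca (uM, `> 0`).
#' @param cth inactivation threshold (uM, `> 0`).
#' @return factor in `(0, 1)`.
#' @export
ca_inactivation_factor <- function(cb, cth) {
  if (any(cb <= 0) || cth <= 0) stop("invalid argument: cb and cth must be positive")
  1 / (1 + (cth / cb)^2)
}

#' Inactivation rates of the L-type channel
#'
#' `a24 = a24o + ACa * FCa(cb)` and `a34 = a34o + ACa * FCa(cb)`; spark-on
#' channels use `FCa = 1`.
#'
#' @param cb junctional Ca (uM).
#' @param params an [ead_params()] (`a24o`, `a34o`, `aca`, `cth`).
#' @param spark_on logical; `TRUE` for channels in an active spark domain.
#' @return named vector `c(a24, a34)` (1/ms).
#' @export
inactivation_rates <- function(cb, params, spark_on = FALSE) {
  f <- if (spark_on) 1 else ca_inactivation_factor(cb, params$cth)
  c(a24 = params$a24o + params$aca * f,
    a34 = params$a34o + params$aca * f)
}

#' L-type channel state occupancies
#'
#' @param occ numeric length-10 vector of occupancies in the order
#'   `C1, C2, O, I1, I2, CS1, CS2, OS, IS1, IS2` (spark-off then spark-on).
#'   Must be nonnegative and sum to 1.
#' @return numeric vector of class `lcc_state`.
#' @export
lcc_state <- function(occ = c(1, rep(0, 9))) {
  stopifnot(length(occ) == 10, all(occ >= -1e-12),
            abs(sum(occ) - 1) < 1e-6)
  names(occ) <- c("C1", "C2", "O", "I1", "I2",
                  "CS1", "CS2", "OS", "IS1", "IS2")
  structure(occ, class = "lcc_state")
}

#' Advance the L-type Markov occupancies
#'
#' Explicit integration of the ten-state master equation at fixed voltage and
#' junctional Ca.  Within each group the scheme is
#' `C1 <-> C2 <-> O <-> I1` with a parallel closed-state inactivation branch
#' `C2 <-> I2`; the spark-off and spark-on groups exchange at the spark
#' recruitment and extinction rates (`alpha_b`, `beta_b`), either between all
#' corresponding states (`couple_all = 1`, a population partition by local
#' environment) or along `O <-> OS` only.
#'
#' @param state an [lcc_state()].
#' @param V membrane voltage (mV).
#' @param cb junctional Ca (uM).
#' @param alpha_b,beta_b group exchange rates (1/ms).
#' @param params an [ead_params()].
#' @param dt substep (ms).
#' @param n_steps number of substeps.
#' @return updated `lcc_state`.
#' @export
step_lcc <- function(state, V, cb, alpha_b, beta_b, params, dt, n_steps = 1) {
  stopifnot(inherits(state, "lcc_state"))
  out <- cpp_lcc_step(unclass(state), V, cb, alpha_b, beta_b,
                      unclass(params), dt, n_steps)
  if (any(out < -1e-6))
    stop("timestep error: occupancy became negative beyond tolerance")
  lcc_state(pmax(out, 0) / sum(pmax(out, 0)) * sum(out))
}

#' L-type current and matching Ca flux
#'
#' Current is proportional to the total open fraction `O + OS` times a
#' constant-field (GHK) driving force; spark-on channels face the local spark
#' Ca concentration.  `jca` is the matching molar flux into the junctional
#' cytosolic compartment (positive influx for inward current).
#'
#' @param state an [lcc_state()].
#' @param V membrane voltage (mV).
#' @param cb junctional Ca (uM).
#' @param params an [ead_params()].
#' @return list with `ical` (uA/uF) and `jca` (uM/ms).
#' @export
lcc_current <- function(state, V, cb, params) {
  stopifnot(inherits(state, "lcc_state"))
  cpp_lcc_current(unclass(state), V, cb, unclass(params))
}
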